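test_that("the network maps 4-band patches to K probability maps", {
  net <- build_network(4L, 5L, "small", seed = 1)
  geo <- snagmap:::net_geometry(32L, 32L, 1L)
  X <- matrix(stats::runif(32 * 32 * 4), 32 * 32, 4)
  fw <- snagmap:::net_forward(net, X, geo)
  expect_equal(dim(fw$probs), c(32L * 32L, 5L))
  expect_true(all(fw$probs > 0 & fw$probs < 1))
  zero <- snagmap:::net_forward(net, X * 0, geo)
  expect_true(all(is.finite(zero$probs)))
})

test_that("eval-mode outputs are identical under batch permutation", {
  net <- build_network(4L, 4L, "small", seed = 2)
  # fold in running stats from a training step so eval mode is exercised
  geo2 <- snagmap:::net_geometry(16L, 16L, 2L)
  set.seed(3)
  Xa <- matrix(stats::runif(16 * 16 * 4), 16 * 16, 4)
  Xb <- matrix(stats::runif(16 * 16 * 4), 16 * 16, 4)
  tr <- snagmap:::net_forward(net, rbind(Xa, Xb), geo2, train = TRUE)
  net$running <- tr$running
  p12 <- snagmap:::net_forward(net, rbind(Xa, Xb), geo2)$probs
  p21 <- snagmap:::net_forward(net, rbind(Xb, Xa), geo2)$probs
  n <- 16L * 16L
  expect_equal(p12[seq_len(n), ], p21[n + seq_len(n), ], tolerance = 1e-12)
  expect_equal(p12[n + seq_len(n), ], p21[seq_len(n), ], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(4)
  net <- build_network(4L, 3L, "small", seed = 5)
  geo <- snagmap:::net_geometry(8L, 8L, 1L)
  X <- matrix(stats::runif(8 * 8 * 4), 8 * 8, 4)
  Tm <- matrix(stats::rbinom(8 * 8 * 3, 1, 0.3), 8 * 8, 3)
  fw <- snagmap:::net_forward(net, X, geo, train = TRUE)
  l <- focal_tversky_loss(fw$probs, Tm, grad = TRUE)
  gr <- snagmap:::net_backward(net, geo, fw$cache, l$dpred)
  eps <- 1e-5
  probe <- list(
    list(c("conv1", "W"), 5L), list(c("conv4", "W"), 10L),
    list(c("conv6", "W"), 100L), list(c("bn3", "gamma"), 4L),
    list(c("bn5", "beta"), 2L), list(c("head", "W"), 2L))
  for (pr in probe) {
    path <- pr[[1]]; i <- pr[[2]]
    for (sgn in c(1, -1)) {
      net2 <- net
      net2$params[[path[1]]][[path[2]]][i] <-
        net$params[[path[1]]][[path[2]]][i] + sgn * eps
      assign(if (sgn > 0) "lp" else "lm",
             focal_tversky_loss(
               snagmap:::net_forward(net2, X, geo, train = TRUE)$probs, Tm))
    }
    num <- (lp - lm) / (2 * eps)
    ana <- gr[[path[1]]][[path[2]]][i]
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("Focal Tversky loss hits its limits and reduces to Dice", {
  set.seed(6)
  Tm <- matrix(stats::rbinom(200 * 3, 1, 0.4), 200, 3)
  expect_equal(focal_tversky_loss(Tm, Tm), 0)

  # independent soft-Dice: 1 - 2TP / (2TP + FP + FN), smoothing 1
  soft_dice <- function(p, t, s = 1) {
    ds <- vapply(seq_len(ncol(p)), function(j) {
      TP <- sum(p[, j] * t[, j])
      FP <- sum(p[, j] * (1 - t[, j])); FN <- sum((1 - p[, j]) * t[, j])
      1 - (TP + s) / (TP + 0.5 * FP + 0.5 * FN + s)
    }, 0)
    mean(ds)
  }
  P <- matrix(stats::runif(200 * 3), 200, 3)
  expect_equal(focal_tversky_loss(P, Tm, alpha = 0.5, beta = 0.5, gamma = 1),
               soft_dice(P, Tm), tolerance = 1e-6)

  # complemented prediction: TI ~ 0 up to smoothing, loss per level ~ 1
  comp <- focal_tversky_loss(1 - Tm, Tm, gamma = 2)
  expect_gt(comp, 0.95)
  expect_lte(comp, 1)
  expect_gte(focal_tversky_loss(P, Tm), 0)

  # empty target, empty prediction: smoothing defines TI = 1, loss 0
  expect_equal(focal_tversky_loss(matrix(0, 10, 2), matrix(0, 10, 2)), 0)
})

test_that("augmentation preserves targets where it must", {
  cfg <- run_config(patch_size = 32L, augment_geometric = 0,
                    augment_spectral = 0)
  p <- make_patch_set(1, cfg, patch_px = 32L, seed = 8)[[1]]
  same <- augment_patch(p, cfg, seed = 1)
  expect_identical(same$image$pixels, p$image$pixels)
  expect_identical(same$target, p$target)

  # spectral-only jitter never touches the target
  cfg_s <- run_config(patch_size = 32L, augment_geometric = 0,
                      augment_spectral = 1)
  sp <- augment_patch(p, cfg_s, seed = 2)
  expect_identical(sp$target, p$target)
  expect_false(identical(sp$image$pixels, p$image$pixels))

  # geometric warp keeps ordinal nesting and the instance count
  cfg_g <- run_config(patch_size = 32L, augment_geometric = 1,
                      augment_spectral = 0)
  gp <- augment_patch(p, cfg_g, seed = 3)
  m <- gp$target
  for (j in 2:dim(m)[3]) expect_true(all(m[, , j] <= m[, , j - 1]))
  expect_equal(gp$truth_count, p$truth_count)
})

test_that("identity affine warp is a no-op", {
  m <- matrix(stats::runif(64), 8, 8)
  out <- snagmap:::affine_warp(list(m), shear = 0, scale = c(1, 1),
                               angle = 0)
  expect_equal(out[[1]], m)
})

test_that("training overfits one patch and tracks the best checkpoint", {
  cfg <- run_config(patch_size = 32L, control_fraction = 0,
                    augment_geometric = 0, augment_spectral = 0)
  p <- make_patch_set(1, cfg, patch_px = 32L,
                      base_params = scene_params(extent_m = 19.2,
                                                 n_crowns = 3,
                                                 clustering = 0),
                      seed = 12)[[1]]
  split <- list(train = list(p), validation = list(p), test = list(p))
  ts <- train_network(split, cfg, epochs = 30, lr = 3e-3, batch_size = 1L,
                      seed = 9, augment = FALSE)
  h <- ts$history
  expect_lt(h$loss[30], h$loss[1])                       # overfit trend
  expect_equal(ts$best_epoch, which.min(h$val_count_mae)[1])
  expect_equal(ts$best_val_count_mae, min(h$val_count_mae))
  expect_lte(min(h$val_count_mae), 1)                    # near-perfect count
  gl <- glance(ts)
  expect_equal(gl$best_epoch, ts$best_epoch)
  expect_equal(nrow(tidy(ts)), 30L)
})

test_that("training is deterministic for a fixed seed", {
  cfg <- run_config(patch_size = 32L)
  patches <- make_patch_set(8, cfg, patch_px = 32L, seed = 14)
  t1 <- train_network(patches, cfg, epochs = 2, batch_size = 2L, seed = 4)
  t2 <- train_network(patches, cfg, epochs = 2, batch_size = 2L, seed = 4)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$net$params, t2$net$params)
})

test_that("non-finite losses abort with diagnostics", {
  cfg <- run_config(patch_size = 32L)
  patches <- make_patch_set(4, cfg, patch_px = 32L, seed = 15)
  split <- list(train = patches[1:2], validation = patches[3],
                test = patches[4])
  bad <- build_network(4L, cfg$energy_levels, "small", seed = 1)
  bad$params$conv1$W[1] <- NaN
  expect_error(train_network(split, cfg, epochs = 1, batch_size = 2L,
                             seed = 1, init_net = bad),
               "non-finite")
})

test_that("prediction is deterministic and stitches tiles consistently", {
  sh <- shared_trained_net()
  net <- sh$ts$net; cfg <- sh$cfg
  b <- generate_scene(scene_params(extent_m = 76.8, n_crowns = 20,
                                   clustering = 0.4), seed = 55)
  whole <- predict_energy(net, b$image, cfg, patch_px = 128L)
  again <- predict_energy(net, b$image, cfg, patch_px = 128L)
  expect_identical(whole$levels, again$levels)
  tiled <- predict_energy(net, b$image, cfg, patch_px = 64L, overlap = 16L)
  agree <- mean(whole$levels == tiled$levels)
  expect_gte(agree, 0.99)
})

test_that("a trained model is quiet on background-only tiles", {
  sh <- shared_trained_net()
  bg <- generate_scene(scene_params(extent_m = 38.4, n_crowns = 0),
                       seed = 77)
  e <- predict_energy(sh$ts$net, bg$image, sh$cfg, patch_px = 64L)
  lab <- watershed_instances(e, min_pixels = sh$cfg$min_pixels)
  expect_equal(max(lab$pixels), 0L)
})

test_that("the trained checkpoint detects crowns on held-out scenes", {
  sh <- shared_trained_net()
  errs <- vapply(1:5, function(s) {
    b <- generate_scene(scene_params(extent_m = 38.4, n_crowns = 6,
                                     clustering = 0.3), seed = 800 + s)
    e <- predict_energy(sh$ts$net, b$image, sh$cfg, patch_px = 64L)
    lab <- watershed_instances(e, min_pixels = sh$cfg$min_pixels)
    abs(max(lab$pixels) - nrow(b$truth_crowns))
  }, 0)
  expect_lte(mean(errs), 2)
})
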