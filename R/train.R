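#' Generate a labelled patch set from synthetic scenes
#'
#' Builds `n_patches` scenes at the configured patch size, including a
#' fraction of background-only control patches, and encodes each truth
#' instance raster as ordinal energy targets. The scene extent follows
#' `patch_px * gsd`.
#'
#' @param n_patches number of patches.
#' @param cfg a [run_config()] (patch size via `patch_size`, K, control
#'   fraction, seed offsets).
#' @param patch_px patch side length in pixels (overrides
#'   `cfg$patch_size`).
#' @param base_params a [scene_params()] template; extent is overridden.
#' @param seed integer seed; patch i uses `seed * 10000 + i`.
#' @return list of patches, each `list(image, instances, energy, target,
#'   truth_count, is_control, seed)`.
#' @export
make_patch_set <- function(n_patches, cfg = run_config(), patch_px = NULL,
                           base_params = NULL, seed = 1L) {
  if (is.null(patch_px)) patch_px <- cfg$patch_size
  if (is.null(base_params)) {
    base_params <- scene_params(extent_m = patch_px * 0.6,
                                n_crowns = max(2L, round(patch_px^2 / 1100)))
  }
  n_control <- round(cfg$control_fraction * n_patches)
  lapply(seq_len(n_patches), function(i) {
    is_control <- i > n_patches - n_control
    p <- base_params
    if (is_control) p$n_crowns <- 0L
    b <- generate_scene(p, seed = seed * 10000L + i)
    e <- instances_to_energy(b$truth_instances, K = cfg$energy_levels,
                             normalisation = cfg$energy_normalisation,
                             quiet = TRUE)
    list(image = b$image, instances = b$truth_instances$pixels[, , 1],
         energy = e, target = energy_to_ordinal(e),
         truth_count = nrow(b$truth_crowns), is_control = is_control,
         seed = b$seed)
  })
}

# Inverse-mapped nearest-neighbour affine warp about the patch centre.
# Applied identically to the image bands and the instance labels; the
# energy/ordinal target is re-encoded from the warped labels so that
# ordinal nesting holds after warping.
affine_warp <- function(mat_list, shear, scale, angle) {
  H <- nrow(mat_list[[1]]); W <- ncol(mat_list[[1]])
  M <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2) %*%
    matrix(c(scale[1], 0, shear, scale[2]), 2, 2)
  Mi <- solve(M)
  rr <- rep(seq_len(H), times = W) - (H + 1) / 2
  cc <- rep(seq_len(W), each = H) - (W + 1) / 2
  sr <- round(Mi[1, 1] * rr + Mi[1, 2] * cc + (H + 1) / 2)
  sc <- round(Mi[2, 1] * rr + Mi[2, 2] * cc + (W + 1) / 2)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  idx <- (sc - 1L) * H + sr
  lapply(mat_list, function(m) {
    out <- matrix(0, H, W)
    out[ok] <- m[idx[ok]]
    out
  })
}

#' Augment one training patch
#'
#' With probability `cfg$augment_geometric`, applies a random affine warp
#' (rotation, shear, scale — emulating off-nadir distortion) jointly to the
#' image and the instance labels, re-encoding the ordinal target from the
#' warped labels. With probability `cfg$augment_spectral`, applies per-band
#' gain and offset jitter to the image only (the target never changes for
#' spectral augmentation).
#'
#' @param patch a patch from [make_patch_set()].
#' @param cfg a [run_config()].
#' @param seed integer seed.
#' @return an augmented patch (same structure).
#' @export
augment_patch <- function(patch, cfg = run_config(), seed = 1L) {
  with_seed(seed, {
    img <- patch$image$pixels
    inst <- patch$instances
    if (stats::runif(1) < cfg$augment_geometric) {
      shear <- stats::runif(1, -0.2, 0.2)
      scale <- stats::runif(2, 0.9, 1.1)
      angle <- stats::runif(1, -pi / 12, pi / 12)
      mats <- affine_warp(c(lapply(1:4, function(b) img[, , b]),
                            list(inst)), shear, scale, angle)
      img <- array(unlist(mats[1:4]), dim = dim(img))
      inst <- matrix(as.integer(round(mats[[5]])), nrow(inst), ncol(inst))
      e <- instances_to_energy(inst, K = cfg$energy_levels,
                               normalisation = cfg$energy_normalisation,
                               quiet = TRUE)
      patch$energy <- e
      patch$target <- energy_to_ordinal(e)
      patch$instances <- inst
      patch$truth_count <- length(setdiff(unique(as.vector(inst)), 0L))
    }
    if (stats::runif(1) < cfg$augment_spectral) {
      gain <- stats::runif(4, 0.85, 1.15)
      off <- stats::runif(4, -10, 10)
      for (b in 1:4)
        img[, , b] <- pmin(255, pmax(0, img[, , b] * gain[b] + off[b]))
    }
    patch$image <- raster_tile(img, patch$image$xmin, patch$image$ymax,
                               patch$image$px, patch$image$crs)
    patch
  })
}

patch_matrix <- function(patches) {
  do.call(rbind, lapply(patches, function(p)
    matrix(p$image$pixels / 255, ncol = 4)))
}

target_matrix <- function(patches, K) {
  do.call(rbind, lapply(patches, function(p) matrix(p$target, ncol = K)))
}

#' Split patches into train / validation / test sets
#' @param patches list from [make_patch_set()].
#' @param ratio three non-negative weights, default 8:1:1.
#' @param seed shuffle seed.
#' @return list of three patch lists (`train`, `validation`, `test`).
#' @export
split_patches <- function(patches, ratio = c(8, 1, 1), seed = 1L) {
  n <- length(patches)
  with_seed(seed, {
    ord <- sample.int(n)
    n_val <- max(1L, round(n * ratio[2] / sum(ratio)))
    n_test <- max(1L, round(n * ratio[3] / sum(ratio)))
    n_train <- n - n_val - n_test
    stopifnot(n_train >= 1)
    list(train = patches[ord[seq_len(n_train)]],
         validation = patches[ord[n_train + seq_len(n_val)]],
         test = patches[ord[n_train + n_val + seq_len(n_test)]])
  })
}

count_from_probs <- function(probs_arr, cfg, min_pixels) {
  e <- monotone_enforce(probs_arr, threshold = cfg$energy_threshold)
  lab <- watershed_instances(e, min_pixels = min_pixels)
  max(lab$pixels)
}

# Validation count MAE: predict each patch, decode, count instances.
validation_count_mae <- function(net, patches, geo1, cfg) {
  K <- net$arch$K
  errs <- vapply(patches, function(p) {
    X <- matrix(p$image$pixels / 255, ncol = 4)
    fw <- net_forward(net, X, geo1, train = FALSE)
    probs <- array(fw$probs, dim = c(nrow(p$image$pixels),
                                     ncol(p$image$pixels), K))
    abs(count_from_probs(probs, cfg, cfg$min_pixels) - p$truth_count)
  }, 0)
  mean(errs)
}

#' Train the segmentation network on a patch set
#'
#' Mini-batch training with the Focal Tversky loss and the Adam optimiser.
#' After every epoch the validation patches are run through the full decode
#' (probabilities -> ordinal enforcement -> watershed -> instance count) and
#' the count MAE against truth is recorded; the checkpoint kept is the one
#' with the lowest validation count MAE seen so far (ties keep the earlier
#' epoch). Training aborts on a non-finite loss.
#'
#' @param patches list from [make_patch_set()], or a pre-made split.
#' @param cfg a [run_config()].
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size patches per gradient step.
#' @param width_preset passed to [build_network()].
#' @param seed seed for split, init, shuffling and augmentation.
#' @param augment apply [augment_patch()] during training.
#' @param init_net optional `snag_net` to warm-start from (replaces the
#'   fresh initialisation).
#' @param verbose print per-epoch progress.
#' @return a `train_state`: `net` (best checkpoint), `final_net`, `history`
#'   tibble (epoch, loss, val_count_mae), `best_epoch`, `split`, `cfg`,
#'   `config_hash`.
#' @export
train_network <- function(patches, cfg = run_config(), epochs = 15L,
                          lr = 3e-3, batch_size = 4L,
                          width_preset = "small", seed = 1L,
                          augment = TRUE, init_net = NULL, verbose = FALSE) {
  split <- if (is.list(patches) && !is.null(patches$train)) patches
  else split_patches(patches, seed = seed)
  K <- cfg$energy_levels
  H <- nrow(split$train[[1]]$image$pixels)
  W <- ncol(split$train[[1]]$image$pixels)
  net <- if (is.null(init_net)) build_network(4L, K, width_preset,
                                              seed = seed) else init_net
  geoB <- net_geometry(H, W, batch_size)
  geo1 <- net_geometry(H, W, 1L)
  opt <- adam_init(net$params)
  n_tr <- length(split$train)
  history <- vector("list", epochs)
  best <- list(mae = Inf, epoch = NA_integer_, net = NULL)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed * 1000L + ep, sample.int(n_tr))
    ep_loss <- 0; n_batches <- 0L
    for (s in seq(1L, n_tr, by = batch_size)) {
      take <- ord[s:min(s + batch_size - 1L, n_tr)]
      batch <- split$train[take]
      if (augment) {
        batch <- lapply(seq_along(batch), function(j)
          augment_patch(batch[[j]], cfg,
                        seed = seed * 100000L + ep * 100L + take[j]))
      }
      geo <- if (length(batch) == batch_size) geoB
      else net_geometry(H, W, length(batch))
      X <- patch_matrix(batch)
      Tm <- target_matrix(batch, K)
      fw <- net_forward(net, X, geo, train = TRUE)
      net$running <- fw$running
      l <- focal_tversky_loss(fw$probs, Tm, cfg$loss_alpha, cfg$loss_beta,
                              cfg$loss_gamma, grad = TRUE)
      if (!is.finite(l$loss))
        stop("non-finite training loss at epoch ", ep,
             " (batch starting at ", s, "); lower the learning rate")
      grads <- net_backward(net, geo, fw$cache, l$dpred)
      st <- adam_step(net$params, grads, opt, lr = lr)
      net$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + l$loss
      n_batches <- n_batches + 1L
    }
    vmae <- validation_count_mae(net, split$validation, geo1, cfg)
    history[[ep]] <- tibble::tibble(epoch = ep,
                                    loss = ep_loss / n_batches,
                                    val_count_mae = vmae)
    if (vmae < best$mae) best <- list(mae = vmae, epoch = ep, net = net)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val count MAE %.3f%s", ep,
                      ep_loss / n_batches, vmae,
                      if (identical(best$epoch, ep)) " *" else ""))
  }
  structure(list(net = best$net, final_net = net,
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, best_val_count_mae = best$mae,
                 split = split, cfg = cfg, config_hash = config_hash(cfg)),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf(
    "<train_state> %d epochs; best epoch %d (val count MAE %.3f)\n",
    nrow(x$history), x$best_epoch, x$best_val_count_mae))
  invisible(x)
}

#' Predict an ordinal energy map for a (possibly large) tile
#'
#' Tiles the raster into network-sized patches with overlap, blends the
#' per-level probabilities of overlapping patches by centre-weighted
#' averaging (weights ramp down towards patch edges, suppressing seam
#' artefacts), and applies [monotone_enforce()] to decode energy levels.
#'
#' @param net a trained `snag_net`.
#' @param tile 4-band `raster_tile` (0-255 DN).
#' @param cfg a [run_config()].
#' @param patch_px network patch size; defaults to the tile size if it is
#'   small, else 128.
#' @param overlap overlap between prediction patches in pixels.
#' @return an `energy_map` for the whole tile.
#' @export
predict_energy <- function(net, tile, cfg = run_config(), patch_px = NULL,
                           overlap = 32L) {
  stopifnot(rt_nbands(tile) >= 4L)
  H <- rt_nrow(tile); W <- rt_ncol(tile)
  K <- net$arch$K
  if (is.null(patch_px))
    patch_px <- if (max(H, W) <= 256L && H %% 4L == 0L && W %% 4L == 0L &&
                    H == W) H else 128L
  if (H == patch_px && W == patch_px) {
    geo <- net_geometry(H, W, 1L)
    fw <- net_forward(net, matrix(tile$pixels[, , 1:4] / 255, ncol = 4),
                      geo, train = FALSE)
    probs <- array(fw$probs, dim = c(H, W, K))
    return(monotone_enforce(probs, cfg$energy_threshold, xmin = tile$xmin,
                            ymax = tile$ymax, px = tile$px, crs = tile$crs))
  }
  patches <- tile_raster(tile, patch_px, overlap)
  geo <- net_geometry(patch_px, patch_px, 1L)
  acc <- array(0, dim = c(max(H, patch_px), max(W, patch_px), K))
  wacc <- matrix(0, dim(acc)[1], dim(acc)[2])
  ramp <- pmin(seq_len(patch_px), rev(seq_len(patch_px)))
  wpatch <- outer(ramp, ramp, pmin)
  for (p in patches) {
    fw <- net_forward(net, matrix(p$pixels[, , 1:4] / 255, ncol = 4),
                      geo, train = FALSE)
    probs <- array(fw$probs, dim = c(patch_px, patch_px, K))
    ro <- p$tags$row_off; co <- p$tags$col_off
    rs <- (ro + 1L):(ro + patch_px); cs <- (co + 1L):(co + patch_px)
    for (j in seq_len(K))
      acc[rs, cs, j] <- acc[rs, cs, j] + probs[, , j] * wpatch
    wacc[rs, cs] <- wacc[rs, cs] + wpatch
  }
  probs <- array(0, dim = c(H, W, K))
  for (j in seq_len(K))
    probs[, , j] <- acc[seq_len(H), seq_len(W), j] / wacc[seq_len(H), seq_len(W)]
  monotone_enforce(probs, cfg$energy_threshold, xmin = tile$xmin,
                   ymax = tile$ymax, px = tile$px, crs = tile$crs)
}
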