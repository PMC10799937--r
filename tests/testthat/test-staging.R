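test_that("worked HSV examples match hand-derived values", {
  s <- stage_scores(c(150, 90, 60))
  expect_equal(s$H, 0.0556, tolerance = 1e-2)
  expect_equal(s$S, 0.600, tolerance = 1e-3)
  expect_equal(s$V, 0.588, tolerance = 1e-3)
  expect_equal(s$Hr, 0.667, tolerance = 1e-2)
  expect_equal(s$X_brown, 0.48, tolerance = 0.01)
  expect_equal(s$X_green, 0)
  expect_equal(s$X_grey, 6.3e-5, tolerance = 0.05)
  expect_equal(s$X_background, 4.3e-3, tolerance = 0.02)
  expect_equal(as.character(classify_stage(s)$stage), "brown")

  g <- stage_scores(c(200, 200, 200))
  expect_equal(g$S, 0)
  expect_equal(g$X_green, 0)
  expect_equal(g$X_brown, 0)
  expect_equal(g$X_grey, 1)
  expect_equal(g$X_background, (1e4^(1 - 200 / 255) - 1) / (1e4 - 1),
               tolerance = 1e-10)
  expect_equal(as.character(classify_stage(g)$stage), "grey")

  k <- stage_scores(c(0, 0, 0))
  expect_equal(k$X_background, 1)
  expect_equal(as.character(classify_stage(k)$stage), "background")
})

test_that("scores agree with an independent oracle across the RGB cube", {
  grid <- seq(0, 255, by = 15)
  combos <- expand.grid(R = grid, G = grid, B = grid)
  s <- stage_scores(combos)
  want <- t(mapply(oracle_stage_scores, combos$R, combos$G, combos$B))
  got <- as.matrix(s[, c("X_green", "X_brown", "X_grey", "X_background")])
  expect_lt(max(abs(got - want)), 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("X_grey decreases in saturation, X_background in value", {
  sat <- stage_scores(tibble::tibble(R = 200, G = seq(200, 80, by = -20),
                                     B = seq(200, 80, by = -20)))
  expect_true(all(diff(sat$X_grey) < 0))
  val <- stage_scores(tibble::tibble(R = seq(20, 240, by = 20),
                                     G = seq(20, 240, by = 20),
                                     B = seq(20, 240, by = 20)))
  expect_true(all(diff(val$X_background) < 0))
})

test_that("red hues above 5/6 wrap and still score brown", {
  s <- stage_scores(c(150, 60, 75))   # magenta-leaning red, H > 5/6
  expect_gt(s$H, 5 / 6)
  expect_gt(s$X_brown, 0)
})

test_that("generator palettes classify perfectly by construction", {
  pal <- scene_params()$palettes
  corners <- function(box) {
    g <- expand.grid(R = box["R", ], G = box["G", ], B = box["B", ])
    rbind(g, data.frame(R = mean(box["R", ]), G = mean(box["G", ]),
                        B = mean(box["B", ])))
  }
  br <- classify_stage(stage_scores(corners(pal$brown)))
  expect_true(all(br$stage == "brown"))
  gr <- classify_stage(stage_scores(corners(pal$grey)))
  expect_true(all(gr$stage == "grey"))
  lv <- classify_stage(stage_scores(corners(pal$live)))
  expect_true(all(lv$stage == "green"))
})

test_that("exact ties resolve grey over brown", {
  sc <- tibble::tibble(X_grey = 0.5, X_brown = 0.5, X_green = 0.1,
                       X_background = 0.1)
  expect_equal(as.character(classify_stage(sc)$stage), "grey")
  all_eq <- tibble::tibble(X_grey = 0.3, X_brown = 0.3, X_green = 0.3,
                           X_background = 0.3)
  expect_equal(as.character(classify_stage(all_eq)$stage), "grey")
})

test_that("literal exponent variant implements the other numerator reading", {
  s <- stage_scores(c(150, 90, 60), literal_exponent = TRUE)
  Hr <- s$Hr
  expect_equal(s$X_brown, 5^(Hr - 1) / 4, tolerance = 1e-12)
})

test_that("mean crown colour honours the one-pixel inner buffer", {
  img <- array(0, dim = c(9, 9, 4))
  lab <- matrix(0L, 9, 9)
  lab[3:7, 3:7] <- 1L
  for (b in 1:4) img[, , b] <- 10 * b
  img[5, 5, 1:3] <- c(150, 90, 60)   # centre differs from edges
  tile <- raster_tile(img, px = 0.6)
  m <- mean_crown_rgb(lab, tile)
  expect_equal(m$n_px_used, 9L)      # 5x5 erodes to 3x3
  expect_equal(m$R, (150 + 8 * 10) / 9)

  lab2 <- matrix(0L, 9, 9); lab2[4:6, 4:6] <- 1L   # 3x3 -> centre pixel
  m2 <- mean_crown_rgb(lab2, tile)
  expect_equal(m2$n_px_used, 1L)
  expect_equal(m2$R, 150)

  lab3 <- matrix(0L, 9, 9); lab3[4:5, 4:5] <- 1L   # 2x2 erodes to empty
  expect_warning(m3 <- mean_crown_rgb(lab3, tile), "eroded")
  expect_equal(m3$n_px_used, 4L)
  expect_true(m3$eroded_empty)
})

test_that("uniform crown colour is returned exactly", {
  img <- array(0, dim = c(12, 12, 4))
  img[, , 1] <- 150; img[, , 2] <- 90; img[, , 3] <- 60
  lab <- matrix(0L, 12, 12); lab[3:10, 3:10] <- 1L
  m <- mean_crown_rgb(lab, raster_tile(img))
  expect_equal(c(m$R, m$G, m$B), c(150, 90, 60))
})

test_that("stage_crowns labels generator scenes 100% correctly", {
  b <- generate_scene(scene_params(extent_m = 76.8, n_crowns = 20,
                                   stage_mix = 0.5), seed = 77)
  cr <- extract_crowns(b$truth_instances, b$image)
  st <- stage_crowns(cr, b$truth_instances, b$image)
  truth <- b$truth_crowns$stage[match(st$id, b$truth_crowns$id)]
  expect_equal(as.character(st$stage), truth)
})

test_that("polygon validation sums gridded counts and filters small areas", {
  spec <- grid_spec(0, 300, 100, ncol = 3, nrow = 3)
  brown <- tibble::tibble(row = c(1L, 1L, 2L), col = c(1L, 2L, 1L),
                          value = c(2, 0, 1))
  polys <- vector_layer(tibble::tibble(
    year = c(2020L, 2020L, 2020L),
    geometry = list(rect_polygon(0, 100, 200, 300),      # covers 4 cells
                    rect_polygon(200, 0, 300, 100),      # all-zero cell
                    rect_polygon(0, 0, 50, 60))))        # 0.3 ha, discarded
  rep <- validate_stage_by_polygons(brown, spec, polys, min_area_ha = 1)
  expect_equal(nrow(rep$per_polygon), 2L)
  expect_equal(rep$per_polygon$brown_total, c(3, 0))
  expect_equal(rep$per_polygon$false_negative, c(FALSE, TRUE))
  expect_equal(rep$false_negative_rate, 0.5)
})
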