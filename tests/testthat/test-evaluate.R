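test_that("count metrics match hand arithmetic and their identities", {
  cc <- count_comparison(obs = c(2, 0, 4), pred = c(1, 1, 4))
  expect_equal(count_mae(cc), 2 / 3)
  expect_equal(relative_total_error(cc), 0)   # errors cancel
  expect_equal(count_bias(cc), 0)

  expect_equal(count_mae(count_comparison(5, 0)), 5)
  expect_equal(relative_total_error(count_comparison(c(2, 4), c(0, 0))), 1)
  expect_equal(count_bias(count_comparison(100, 96)), 4)
  expect_equal(count_bias(count_comparison(100, 110)), -10)

  perfect <- count_comparison(1:5, 1:5)
  expect_equal(count_mae(perfect), 0)
  expect_equal(relative_total_error(perfect), 0)
  expect_equal(count_bias(perfect), 0)
  expect_true(is.na(count_bias(count_comparison(c(0, 0), c(1, 0)))))
})

test_that("MAE bounds |ME| and rTE vanishes iff bias does", {
  set.seed(8)
  for (i in 1:25) {
    cc <- count_comparison(rpois(10, 4), rpois(10, 4))
    expect_gte(count_mae(cc), abs(mean(cc$obs - cc$pred)))
    rte <- relative_total_error(cc)
    bias <- count_bias(cc)
    expect_equal(rte == 0, bias == 0)
    expect_equal(abs(bias), 100 * rte, tolerance = 1e-10)
  }
})

test_that("IoU scores cover exact, partial, disjoint and absent classes", {
  a <- matrix(0L, 10, 10); a[3:6, 3:6] <- 1L
  same <- iou_scores(a, a)
  expect_equal(same$IoU, c(1, 1))
  expect_equal(miou(same), 1)

  # two unit squares overlapping half their area: IoU = 0.5 / 1.5 = 1/3
  b <- matrix(0L, 10, 10); b[3:6, 5:8] <- 1L
  half <- iou_scores(a, b, classes = 1L)
  expect_equal(half$IoU, 1 / 3)

  c2 <- matrix(0L, 10, 10); c2[8:9, 8:9] <- 1L
  expect_equal(iou_scores(a, c2, classes = 1L)$IoU, 0)

  zero <- matrix(0L, 4, 4)
  expect_equal(iou_scores(zero, zero, classes = c(0L, 1L))$IoU, c(1, 1))
  dropped <- iou_scores(zero, zero, classes = c(0L, 1L),
                        absent_class = "drop")
  expect_true(is.na(dropped$IoU[2]))
  expect_equal(miou(dropped), 1)
})

test_that("tree matching applies the 6 m buffer and >50% coverage rules", {
  crowns <- tibble::tibble(
    id = 1L, cx = 0, cy = 0,
    polygon = list(ellipse_polygon(0, 0, 2, 2, n = 128)))
  obs <- vector_layer(tibble::tibble(
    year = c(2019L, 2019L),
    geometry = list(c(5, 0), c(9, 0))))
  m <- match_trees(crowns, obs, buffer_m = 6)
  expect_equal(m$per_observation$matched, c(TRUE, FALSE))
  expect_equal(m$by_year$matched_pct, 50)
  expect_equal(m$by_year$bias_pct, 50)

  # coverage fractions behind the >50% rule are computed correctly: a crown
  # square ending at x = -10.2 with a 6 m buffer covers the [-10, 10] strip
  # up to x = -4.2, i.e. 29% of it; with a 16 m buffer up to 5.8, i.e. 79%
  crown_sq <- list(rect_polygon(-20, 0, -10.2, 10))
  f29 <- coverage_fraction(rect_polygon(-10, 0, 10, 10), crown_sq,
                           buffer_m = 6, res = 0.1)
  f79 <- coverage_fraction(rect_polygon(-10, 0, 10, 10), crown_sq,
                           buffer_m = 16, res = 0.1)
  expect_equal(f29, 0.29, tolerance = 0.02)
  expect_equal(f79, 0.79, tolerance = 0.02)
})

test_that("polygon observations match iff buffered crowns cover >50%", {
  # crown strip whose 6 m buffer covers 55% of the observed square
  crowns <- tibble::tibble(id = 1L, cx = 2, cy = 5,
                           polygon = list(rect_polygon(0, 0, 5, 10)))
  obs_in <- vector_layer(tibble::tibble(
    year = 2019L, geometry = list(rect_polygon(1, 0, 20.5, 10))))
  m1 <- match_trees(crowns, obs_in, buffer_m = 6, coverage_res = 0.1)
  expect_true(m1$per_observation$matched)   # covered to x = 11 -> 51.3%
  obs_out <- vector_layer(tibble::tibble(
    year = 2019L, geometry = list(rect_polygon(1, 0, 23, 10))))
  m2 <- match_trees(crowns, obs_out, buffer_m = 6, coverage_res = 0.1)
  expect_false(m2$per_observation$matched)  # covered to x = 11 of 22 -> 45%
})

test_that("plot comparisons count centroids inside buffered plots", {
  crowns <- tibble::tibble(id = 1:3, cx = c(5, 15, 30), cy = c(5, 5, 5))
  plots <- vector_layer(tibble::tibble(
    count = 3, year = 2016L,
    geometry = list(rect_polygon(0, 0, 10, 10))))
  cc <- compare_plots(crowns, plots, buffer_m = 6)
  expect_equal(cc$pred, 2L)   # (15,5) is 5 m outside -> inside the buffer
  expect_equal(cc$obs, 3)
  cc0 <- compare_plots(crowns, plots, buffer_m = 1)
  expect_equal(cc0$pred, 1L)
  expect_warning(
    compare_plots(crowns, vector_layer(tibble::tibble(
      count = c(1, 1), year = 2016L,
      geometry = list(rect_polygon(0, 0, 10, 10),
                      rect_polygon(5, 5, 15, 15)))), buffer_m = 0),
    "overlap")
})

test_that("census points with DBH filters produce observed counts", {
  plots <- vector_layer(tibble::tibble(
    year = 2016L, geometry = list(rect_polygon(0, 0, 20, 20))))
  census <- vector_layer(tibble::tibble(
    plot = 1L, dbh_cm = c(50, 30, 45),
    geometry = list(c(5, 5), c(6, 6), c(7, 7))))
  crowns <- tibble::tibble(id = 1:2, cx = c(5, 6), cy = c(5, 6))
  cc <- compare_plots(crowns, plots, census = census, dbh_min_cm = 40)
  expect_equal(cc$obs, 2)   # the 30 cm tree is filtered out
  expect_equal(cc$pred, 2L)
})

test_that("a perfect detector achieves ideal values on generator truth", {
  b <- generate_scene(scene_params(extent_m = 76.8, n_crowns = 15), seed = 5)
  cr <- extract_crowns(b$truth_instances, b$image)
  spec <- grid_for_tile(b$truth_instances, 38.4)
  truth_counts <- count_grid(cr, spec)
  cc <- count_comparison(truth_counts$value, truth_counts$value)
  expect_equal(count_mae(cc), 0)
  expect_equal(count_bias(cc), 0)
  mask <- (b$truth_instances$pixels[, , 1] > 0) * 1L
  expect_equal(miou(iou_scores(mask, mask)), 1)
})

test_that("stratified bias recombines into the overall bias", {
  set.seed(12)
  cc <- count_comparison(obs = rpois(40, 5), pred = rpois(40, 4))
  locs <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  fire <- vector_layer(tibble::tibble(
    year = 2020L, agents = list("fire"), kind = "fire",
    geometry = list(rect_polygon(0, 0, 50, 100))))
  tab <- stratified_bias(cc, locs, fire)
  expect_setequal(tab$stratum, c("fire", "non_fire", "overall"))
  w <- tab$obs_total[1:2] / sum(tab$obs_total[1:2])
  expect_equal(sum(w * tab$bias_pct[1:2]), tab$bias_pct[3],
               tolerance = 1e-10)
})

test_that("tidy and glance methods expose the evaluation tables", {
  cc <- count_comparison(obs = c(2, 0, 4), pred = c(1, 1, 4))
  td <- tidy(cc)
  expect_equal(td$error, c(1, -1, 0))
  gl <- glance(cc)
  expect_equal(gl$mae, 2 / 3)
  expect_equal(gl$bias_pct, 0)
  sc <- iou_scores(matrix(1L, 2, 2), matrix(1L, 2, 2))
  expect_equal(glance(sc)$miou, 1)
})

test_that("a detectability-0.8 survey over 75 plots measures ~20% bias", {
  b <- generate_scene(scene_params(extent_m = 420, n_crowns = 300,
                                   clustering = 0.3), seed = 7)
  cr <- extract_crowns(b$truth_instances)
  # 75 plots of 24 x 24 m inset in a 30 m lattice
  cells <- utils::head(expand.grid(i = 0:13, j = 0:13), 75)
  polys <- lapply(seq_len(75), function(k)
    rect_polygon(cells$i[k] * 30 + 3, cells$j[k] * 30 + 3,
                 cells$i[k] * 30 + 27, cells$j[k] * 30 + 27))
  obs <- vapply(polys, function(p)
    sum(dist_to_geom(cr$cx, cr$cy, p) <= 6), 0L)
  plots <- vector_layer(tibble::tibble(count = obs, year = 2016L,
                                       geometry = polys))
  # Monte-Carlo over independent survey realisations of the same plots
  set.seed(11)
  biases <- vapply(1:10, function(r) {
    detected <- cr[runif(nrow(cr)) < 0.8, ]
    suppressWarnings(cc <- compare_plots(detected, plots, buffer_m = 6))
    count_bias(cc)
  }, 0)
  expect_equal(mean(biases), 20, tolerance = 5 / 20)
})
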