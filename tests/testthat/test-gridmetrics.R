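mk_crowns <- function(cx, cy, area = 50, stage = "grey") {
  tibble::tibble(id = seq_along(cx), cx = cx, cy = cy,
                 area_m2 = rep_len(area, length(cx)),
                 stage = rep_len(stage, length(cx)))
}

test_that("count grids count centroids and apply mean-error correction", {
  spec <- grid_spec(0, 200, 100, ncol = 2, nrow = 2)
  cr <- mk_crowns(c(10, 20, 30), c(190, 180, 170))
  raw <- count_grid(cr, spec)
  expect_equal(nrow(raw), 1L)
  expect_equal(raw$value, 3)
  expect_false(attr(raw, "bias_corrected"))

  bias <- structure(list(me_per_ha = 0.56, F = 10, n = 3, source = "v"),
                    class = "bias_model")
  corr <- count_grid(cr, spec, bias)
  expect_true(attr(corr, "bias_corrected"))
  expect_equal(nrow(corr), 4L)   # every cell in the mapped footprint
  cell <- dplyr::filter(corr, row == 1, col == 1)
  expect_equal(cell$value, 3.56)  # +0.56 trees/ha on a 1 ha cell
  empty <- dplyr::filter(corr, row == 2, col == 2)
  expect_equal(empty$value, 0.56)
})

test_that("centroids on shared cell edges are counted exactly once", {
  spec <- grid_spec(0, 200, 100, ncol = 2, nrow = 2)
  cr <- mk_crowns(100, 150)   # exactly on the vertical cell boundary
  g <- count_grid(cr, spec)
  expect_equal(sum(g$value), 1)
  expect_equal(g$col, 2L)     # half-open: belongs to the right cell
})

test_that("bias correction at 30 m is refused", {
  spec <- grid_spec(0, 60, 30, ncol = 2, nrow = 2)
  bias <- structure(list(me_per_ha = 1, F = 10, n = 3, source = "v"),
                    class = "bias_model")
  expect_error(count_grid(mk_crowns(10, 50), spec, bias), "30 m")
})

test_that("mean error estimation follows the patch-to-hectare scale", {
  cc <- count_comparison(obs = c(5, 3, 4), pred = c(4, 3, 3))
  b <- estimate_bias(cc, patch_area_ha = 0.1)
  expect_equal(b$F, 10)
  expect_equal(b$me_per_ha, 10 * 2 / 3)
  expect_equal(estimate_bias(count_comparison(1:3, 1:3), 0.1)$me_per_ha, 0)
})

test_that("bias-corrected totals recover truth under systematic undercount", {
  # ME calibrated on one patch set, applied to an independent one
  set.seed(42)
  n <- 1000
  sim <- function() {
    truth <- rpois(n, 6)
    list(truth = truth, pred = truth - pmin(truth, rpois(n, 0.3)))
  }
  calib <- sim()
  b <- estimate_bias(count_comparison(calib$truth, calib$pred),
                     patch_area_ha = 0.1)
  held <- sim()
  corrected_total <- sum(held$pred) + n * b$me_per_ha * 0.1
  expect_lt(abs(corrected_total - sum(held$truth)) / sum(held$truth), 0.02)
})

test_that("bias correction changes the total by n_cells x ME x cell_ha", {
  spec <- grid_spec(0, 300, 100, ncol = 3, nrow = 3)
  cr <- mk_crowns(runif(20, 0, 300), runif(20, 0, 300))
  bias <- structure(list(me_per_ha = 0.4, F = 10, n = 5, source = "v"),
                    class = "bias_model")
  raw <- count_grid(cr, spec)
  corr <- count_grid(cr, spec, bias)
  expect_equal(sum(corr$value) - sum(raw$value), 9 * 0.4)
})

test_that("percent mortality handles zero baselines and clamps overshoot", {
  spec <- grid_spec(0, 480, 240, ncol = 2, nrow = 2)
  dead <- tibble::tibble(row = c(1L, 1L, 2L), col = c(1L, 2L, 1L),
                         value = c(5, 3, 120))
  base <- tibble::tibble(row = c(1L, 1L, 2L), col = c(1L, 2L, 1L),
                         value = c(100, 0, 100))
  expect_warning(pm <- percent_mortality(dead, base, spec), "clamped")
  expect_equal(pm$value[pm$row == 1 & pm$col == 1], 5)
  expect_true(is.na(pm$value[pm$row == 1 & pm$col == 2]))
  expect_equal(pm$value[pm$row == 2 & pm$col == 1], 100)
  bad <- grid_spec(10, 480, 240, ncol = 2, nrow = 2)
  expect_error(percent_mortality(dead, base, spec, bad), "misaligned")
})

test_that("canopy metrics aggregate area and median size per hectare cell", {
  spec <- grid_spec(0, 100, 100, ncol = 1, nrow = 1)
  cr <- mk_crowns(c(50, 60), c(50, 60), area = c(50, 150))
  cm <- canopy_metrics(cr, spec)
  expect_equal(cm$dead_canopy_pct$value, 2)
  expect_equal(cm$median_crown_size$value, 100)
  big <- canopy_metrics(mk_crowns(50, 50, area = 10000), spec)
  expect_equal(big$dead_canopy_pct$value, 100)
  none <- canopy_metrics(mk_crowns(numeric(0), numeric(0)), spec)
  expect_equal(nrow(none$dead_canopy_pct), 0L)
})

test_that("brown percentage applies the single-brown noise rule", {
  spec <- grid_spec(0, 100, 100, ncol = 1, nrow = 1)
  cr <- mk_crowns(runif(4, 0, 100), runif(4, 0, 100),
                  stage = c("brown", "brown", "grey", "grey"))
  expect_equal(brown_pct_grid(cr, spec)$value, 50)
  cr1 <- mk_crowns(runif(4, 0, 100), runif(4, 0, 100),
                   stage = c("brown", "grey", "grey", "grey"))
  expect_equal(brown_pct_grid(cr1, spec)$value, 0)
  expect_equal(nrow(brown_pct_grid(cr1, spec, drop_single_brown = TRUE)), 0L)
  expect_equal(nrow(brown_pct_grid(mk_crowns(numeric(0), numeric(0)), spec)),
               0L)
})

test_that("three-prong composition normalises by 2nd/98th percentiles", {
  spec <- grid_spec(0, 1000, 100, ncol = 10, nrow = 10)
  cells <- tidyr::expand_grid(row = 1:10, col = 1:10)
  set.seed(3)
  mk <- function(v) dplyr::mutate(cells, value = v)
  count <- mk(runif(100, 0, 50))
  brown <- mk(runif(100, 0, 100))
  size <- mk(runif(100, 10, 200))
  arr <- three_prong_map(count, brown, size, spec)
  expect_equal(dim(arr$pixels), c(10L, 10L, 3L))
  expect_true(all(arr$pixels >= 0 & arr$pixels <= 1))
  hi <- which.max(count$value)
  expect_equal(arr$pixels[count$row[hi], count$col[hi], 1], 1)
  expect_warning(cst <- three_prong_map(mk(rep(5, 100)), brown, size, spec),
                 "constant")
  expect_true(all(cst$pixels[, , 1] == 0.5))
})

test_that("cluster-size profile matches hand bookkeeping", {
  counts <- structure(tibble::tibble(row = c(1L, 1L, 2L),
                                     col = c(1L, 2L, 1L),
                                     value = c(1, 1, 3)),
                      bias_corrected = FALSE)
  tab <- cluster_size_profile(counts)
  expect_equal(tab$k, c(1L, 3L))
  expect_equal(tab$n_cells, c(2L, 1L))
  expect_equal(tab$n_trees, c(2, 3))
  expect_equal(tab$cum_pct, c(40, 100))
  empty <- cluster_size_profile(
    structure(tibble::tibble(row = integer(), col = integer(),
                             value = numeric()), bias_corrected = FALSE))
  expect_equal(nrow(empty), 0L)
  expect_error(cluster_size_profile(
    structure(counts, bias_corrected = TRUE)), "raw")
})

test_that("30 m counts conserve crowns and nest into 240 m blocks", {
  b <- generate_scene(scene_params(extent_m = 240, n_crowns = 60,
                                   clustering = 0.5), seed = 61)
  cr <- extract_crowns(b$truth_instances)
  s30 <- grid_for_tile(b$truth_instances, 30)
  s240 <- grid_for_tile(b$truth_instances, 240)
  c30 <- count_grid(cr, s30)
  c240 <- count_grid(cr, s240)
  expect_equal(sum(c30$value), nrow(cr))
  expect_equal(sum(c240$value), nrow(cr))
  # 240 m counts equal block sums of the nested 8x8 blocks of 30 m cells
  blocks <- dplyr::mutate(c30, brow = (row - 1) %/% 8 + 1,
                          bcol = (col - 1) %/% 8 + 1) |>
    dplyr::group_by(brow, bcol) |>
    dplyr::summarise(value = sum(value), .groups = "drop")
  joined <- dplyr::full_join(blocks, c240,
                             by = c(brow = "row", bcol = "col"))
  expect_equal(joined$value.x, joined$value.y)
})
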