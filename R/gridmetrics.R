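#' Mean-error bias model for gridded counts
#'
#' `ME = F * mean(Y_obs - Y_pred)` with `F = 1 / patch_area_ha` the factor
#' converting a patch or plot count to a per-hectare count. Adding the ME to
#' gridded counts stops patch-level systematic error from propagating into
#' regional totals. Positive ME means the detector undercounts.
#'
#' @param comparison a [count_comparison()] (columns `obs`, `pred`).
#' @param patch_area_ha area of one comparison unit in hectares.
#' @param source label recording which comparison set produced the model.
#' @return a `bias_model` list with `me_per_ha`, `F`, `n`, `source`.
#' @export
estimate_bias <- function(comparison, patch_area_ha, source = "validation") {
  stopifnot(patch_area_ha > 0, nrow(comparison) >= 1)
  F <- 1 / patch_area_ha
  me <- F * mean(comparison$obs - comparison$pred)
  structure(list(me_per_ha = me, F = F, n = nrow(comparison),
                 source = source), class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model> ME = %+.3f trees/ha (F = %g, n = %d, %s)\n",
              x$me_per_ha, x$F, x$n, x$source))
  invisible(x)
}

#' Gridded dead-tree counts, optionally bias-corrected
#'
#' Counts crown centroids per cell (half-open cell intervals: a centroid on
#' a shared edge lands in exactly one cell). With a `bias` model, the ME is
#' scaled to the cell area and added to every cell of the grid (the grid is
#' assumed to cover the mapped footprint); 30 m grids must stay raw, so
#' supplying a bias model with a 30 m spec is an error.
#'
#' @param crowns a `crown_records` tibble.
#' @param spec a `grid_spec`.
#' @param bias optional `bias_model` from [estimate_bias()].
#' @return tibble with `row`, `col`, `value`; attributes `bias_corrected`
#'   and `spec`. Raw counts include only occupied cells; bias-corrected
#'   output covers every cell.
#' @export
count_grid <- function(crowns, spec, bias = NULL) {
  if (!is.null(bias) && spec$cell_size == 30)
    stop("bias correction must not be applied to 30 m count grids")
  cells <- grid_cell(spec, crowns$cx, crowns$cy)
  counts <- dplyr::filter(cells, !is.na(.data$row)) |>
    dplyr::count(.data$row, .data$col, name = "value")
  counts$value <- as.numeric(counts$value)
  if (!is.null(bias)) {
    cell_ha <- spec$cell_size^2 / 1e4
    all_cells <- tidyr::expand_grid(row = seq_len(spec$nrow),
                                    col = seq_len(spec$ncol))
    counts <- dplyr::left_join(all_cells, counts, by = c("row", "col"))
    counts$value[is.na(counts$value)] <- 0
    counts$value <- counts$value + bias$me_per_ha * cell_ha
  }
  structure(counts, bias_corrected = !is.null(bias), spec = spec,
            metric = "dead_tree_count",
            class = c("grid_metric", class(tibble::tibble())))
}

#' Percent tree mortality against a baseline live-tree count
#'
#' `100 * dead / baseline` per cell on aligned grids (conventionally 240 m).
#' Cells with baseline 0 become NA; values above 100 against a noisy
#' baseline are clamped to 100 with a warning.
#'
#' @param counts count tibble (`row`, `col`, `value`) on `spec`.
#' @param baseline baseline tibble (`row`, `col`, `value`), same grid.
#' @param spec the shared `grid_spec` (for misalignment checks).
#' @param baseline_spec optional `grid_spec` of the baseline; must equal
#'   `spec`.
#' @return tibble with `row`, `col`, `value` (percent in [0, 100]).
#' @export
percent_mortality <- function(counts, baseline, spec,
                              baseline_spec = NULL) {
  if (!is.null(baseline_spec)) {
    same <- isTRUE(all.equal(spec[c("x0", "y0", "cell_size", "ncol", "nrow")],
                             baseline_spec[c("x0", "y0", "cell_size",
                                             "ncol", "nrow")]))
    if (!same) stop("count and baseline grids are misaligned")
  }
  joined <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(counts), dead = "value"),
    dplyr::rename(tibble::as_tibble(baseline), base = "value"),
    by = c("row", "col"))
  joined$value <- ifelse(joined$base > 0, 100 * joined$dead / joined$base,
                         NA_real_)
  n_over <- sum(joined$value > 100, na.rm = TRUE)
  if (n_over > 0) {
    warning(n_over, " cell(s) exceed 100% mortality vs baseline; clamped")
    joined$value <- pmin(joined$value, 100)
  }
  structure(dplyr::select(joined, "row", "col", "value"),
            spec = spec, metric = "percent_mortality",
            class = c("grid_metric", class(tibble::tibble())))
}

#' Dead-canopy percentage and median crown size per cell
#'
#' Whole crown areas are assigned to the cell containing the centroid
#' (crowns spanning cells are not split). Dead-canopy percent is
#' `100 * sum(area_m2) / cell_area`; the companion layer is the median crown
#' size in the same assignment.
#'
#' @param crowns a `crown_records` tibble.
#' @param spec a `grid_spec` (conventionally 100 m cells).
#' @return list of two tibbles `dead_canopy_pct` and `median_crown_size`,
#'   each `row`, `col`, `value` over occupied cells.
#' @export
canopy_metrics <- function(crowns, spec) {
  cell_area <- spec$cell_size^2
  cells <- dplyr::bind_cols(tibble::as_tibble(crowns)["area_m2"],
                            grid_cell(spec, crowns$cx, crowns$cy))
  cells <- dplyr::filter(cells, !is.na(.data$row))
  agg <- dplyr::group_by(cells, .data$row, .data$col) |>
    dplyr::summarise(total = sum(.data$area_m2),
                     med = stats::median(.data$area_m2), .groups = "drop")
  mk <- function(v, metric) structure(
    tibble::tibble(row = agg$row, col = agg$col, value = v),
    spec = spec, metric = metric,
    class = c("grid_metric", class(tibble::tibble())))
  list(dead_canopy_pct = mk(pmin(100, 100 * agg$total / cell_area),
                            "dead_canopy_pct"),
       median_crown_size = mk(agg$med, "median_crown_size_m2"))
}

#' Brown-stage percentage per cell with the single-tree noise rule
#'
#' `100 * brown / total` dead trees per cell; cells with exactly one
#' brown-stage tree are set to 0% (single brown trees are treated as
#' classification noise; set `drop_single_brown = TRUE` to drop those cells
#' from the table instead). Cells with no dead trees do not appear.
#'
#' @param crowns staged `crown_records` (stage column filled).
#' @param spec a `grid_spec` (conventionally 100 m cells).
#' @param drop_single_brown drop single-brown cells instead of zeroing.
#' @return tibble `row`, `col`, `value`, `n_dead`, `n_brown`.
#' @export
brown_pct_grid <- function(crowns, spec, drop_single_brown = FALSE) {
  cells <- dplyr::bind_cols(
    tibble::as_tibble(crowns)["stage"],
    grid_cell(spec, crowns$cx, crowns$cy)) |>
    dplyr::filter(!is.na(.data$row))
  agg <- dplyr::group_by(cells, .data$row, .data$col) |>
    dplyr::summarise(n_dead = dplyr::n(),
                     n_brown = sum(.data$stage == "brown"),
                     .groups = "drop") |>
    dplyr::mutate(value = 100 * .data$n_brown / .data$n_dead)
  single <- agg$n_brown == 1L
  if (drop_single_brown) {
    agg <- agg[!single, ]
  } else {
    agg$value[single] <- 0
  }
  structure(dplyr::select(agg, "row", "col", "value", "n_dead", "n_brown"),
            spec = spec, metric = "brown_stage_pct",
            class = c("grid_metric", class(tibble::tibble())))
}

#' Compose the three-prong hotspot map
#'
#' Stacks count, brown-stage percentage and median crown size into an RGB
#' raster, each band linearly rescaled between its own 2nd and 98th
#' percentile over valid cells and clamped to [0, 1]. High count + high
#' brown + high size renders white; high count and size with low brown
#' renders magenta. A constant band (p2 = p98) is set to 0.5.
#'
#' @param count,brown_pct,median_size aligned grid-metric tibbles
#'   (`row`, `col`, `value`) on the same `grid_spec`.
#' @param spec the shared `grid_spec`.
#' @return 3-band `raster_tile` in [0, 1]; cells where any band is missing
#'   are 0 in all bands.
#' @export
three_prong_map <- function(count, brown_pct, median_size, spec) {
  rescale <- function(df) {
    v <- df$value
    p <- stats::quantile(v, c(0.02, 0.98), na.rm = TRUE, names = FALSE)
    if (p[1] == p[2]) {
      warning("constant layer (p2 = p98); band set to 0.5")
      df$value <- rep(0.5, length(v))
    } else {
      df$value <- pmin(1, pmax(0, (v - p[1]) / (p[2] - p[1])))
    }
    df
  }
  bands <- lapply(list(count, brown_pct, median_size), function(df)
    rescale(tibble::as_tibble(df)[c("row", "col", "value")]))
  full <- Reduce(function(a, b) dplyr::inner_join(a, b, by = c("row", "col")),
                 bands)
  arr <- array(0, dim = c(spec$nrow, spec$ncol, 3))
  for (k in 1:3)
    arr[cbind(full$row, full$col, k)] <- full[[k + 2L]]
  raster_tile(arr, xmin = spec$x0, ymax = spec$y0, px = spec$cell_size,
              crs = spec$crs,
              tags = list(metric = "three_prong",
                          bands = "count,brown_pct,median_size"))
}

#' Cluster-size profile of a raw 30 m count grid
#'
#' Histogram of cells by their dead-tree count k, with the number of trees
#' in those cells and the cumulative share of all trees found in cells with
#' at most k trees. Cells with k = 1 are the isolated dead trees that
#' coarser products tend to miss.
#'
#' @param counts raw (non-bias-corrected) count tibble (`row`, `col`,
#'   `value`).
#' @return tibble `k`, `n_cells`, `n_trees`, `cum_pct`.
#' @export
cluster_size_profile <- function(counts) {
  if (isTRUE(attr(counts, "bias_corrected")))
    stop("cluster-size profile requires raw (non-bias-corrected) counts")
  v <- counts$value[counts$value > 0]
  if (!length(v)) {
    return(tibble::tibble(k = integer(), n_cells = integer(),
                          n_trees = numeric(), cum_pct = numeric()))
  }
  tab <- tibble::tibble(k = as.integer(sort(unique(v))))
  tab$n_cells <- vapply(tab$k, function(k) sum(v == k), 0L)
  tab$n_trees <- tab$k * tab$n_cells
  tab$cum_pct <- 100 * cumsum(tab$n_trees) / sum(tab$n_trees)
  tab
}
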