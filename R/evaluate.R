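#' Paired observed/predicted counts
#'
#' One row per comparison unit (a labelled patch or a field plot). All the
#' count accuracy statistics — MAE, relative total error, count bias and the
#' mean-error bias model — are computed from this table.
#'
#' @param obs,pred non-negative observed and predicted counts.
#' @param unit optional unit identifiers.
#' @param area_ha optional unit areas in hectares.
#' @param year optional survey year per unit.
#' @return a `count_comparison` tibble.
#' @export
count_comparison <- function(obs, pred, unit = seq_along(obs),
                             area_ha = NA_real_, year = NA_integer_) {
  stopifnot(length(obs) == length(pred), length(obs) >= 1,
            all(obs >= 0), all(pred >= 0))
  structure(tibble::tibble(unit = unit, obs = as.numeric(obs),
                           pred = as.numeric(pred),
                           area_ha = area_ha, year = year),
            class = c("count_comparison", class(tibble::tibble())))
}

#' Mean absolute error of counts
#'
#' `MAE = mean(|obs - pred|)`, in trees per unit (per patch, per plot, or
#' per hectare if the inputs are densities).
#'
#' @param comparison a [count_comparison()].
#' @return scalar MAE.
#' @export
count_mae <- function(comparison) mean(abs(comparison$obs - comparison$pred))

#' Relative total error of counts
#'
#' `rTE = |sum(obs - pred)| / |sum(obs)|`: errors of opposite sign cancel,
#' so a model can have a substantial MAE and still a near-zero rTE (and
#' vice versa). Undefined (NA) when the observed total is zero.
#'
#' @param comparison a [count_comparison()].
#' @return scalar fraction, or NA.
#' @export
relative_total_error <- function(comparison) {
  tot <- sum(comparison$obs)
  if (tot == 0) return(NA_real_)
  abs(sum(comparison$obs - comparison$pred)) / abs(tot)
}

#' Count bias (percent, positive = underestimation)
#'
#' `bias = 100 * sum(obs - pred) / sum(obs)`. Positive values mean the
#' detector undercounts. Undefined (NA) when the observed total is zero.
#'
#' @param comparison a [count_comparison()].
#' @return scalar percent, or NA.
#' @export
count_bias <- function(comparison) {
  tot <- sum(comparison$obs)
  if (tot == 0) return(NA_real_)
  100 * sum(comparison$obs - comparison$pred) / tot
}

#' Per-class IoU and mean IoU of two class rasters
#'
#' `IoU = TP / (TP + FP + FN)` in pixels per class, and the mean over the
#' `k` classes. A class absent from both rasters (e.g. the dead class on a
#' control patch) is scored 1 by convention (`absent_class`), or excluded
#' with `absent_class = "drop"`.
#'
#' @param pred,label integer class matrices (same shape, same class set).
#' @param classes class values scored; default the union of both rasters.
#' @param absent_class `"one"` (IoU = 1) or `"drop"`.
#' @return a `segmentation_scores` tibble: `class`, `TP`, `FP`, `FN`,
#'   `IoU`; attribute `miou`.
#' @export
iou_scores <- function(pred, label, classes = NULL,
                       absent_class = c("one", "drop")) {
  absent_class <- match.arg(absent_class)
  stopifnot(all(dim(pred) == dim(label)))
  if (is.null(classes)) classes <- sort(unique(c(pred, label)))
  rows <- lapply(classes, function(cl) {
    p <- pred == cl; l <- label == cl
    tp <- sum(p & l); fp <- sum(p & !l); fn <- sum(!p & l)
    iou <- if (tp + fp + fn == 0) {
      if (absent_class == "drop") NA_real_ else 1
    } else tp / (tp + fp + fn)
    tibble::tibble(class = cl, TP = tp, FP = fp, FN = fn, IoU = iou)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, miou = mean(out$IoU, na.rm = TRUE),
            class = c("segmentation_scores", class(tibble::tibble())))
}

#' Mean IoU of a `segmentation_scores` table
#' @param scores from [iou_scores()].
#' @return scalar mean IoU.
#' @export
miou <- function(scores) attr(scores, "miou")

#' Match field observations to predicted crowns (6 m buffer rule)
#'
#' Each predicted crown polygon is buffered by `buffer_m` (to absorb
#' image georeferencing error). An observation *point* matches if it falls
#' inside any buffered crown (equivalently, lies within `buffer_m` of a
#' crown polygon); an observed crown *polygon* matches if the buffered
#' predicted crowns cover more than half of its area. The tree-level bias is
#' the percentage of observations left unmatched (positive =
#' underestimation); the matched percentage is reported alongside.
#'
#' @param crowns a `crown_records` tibble.
#' @param observations a `vector_layer` of points and/or polygons with an
#'   optional `year` column.
#' @param buffer_m buffer distance in metres.
#' @param coverage_res rasterisation step for polygon coverage, metres.
#' @return list with `per_observation` tibble (`obs`, `year`, `type`,
#'   `matched`) and `by_year` tibble (`year`, `n`, `matched_pct`,
#'   `bias_pct`).
#' @export
match_trees <- function(crowns, observations, buffer_m = 6,
                        coverage_res = 0.25) {
  geoms <- crowns$polygon
  matched <- vapply(seq_len(nrow(observations)), function(i) {
    g <- observations$geometry[[i]]
    if (is_point_geom(g)) {
      if (!length(geoms)) return(FALSE)
      any(vapply(geoms, function(cr)
        dist_to_geom(g[1], g[2], cr) <= buffer_m, TRUE))
    } else {
      coverage_fraction(g, geoms, buffer_m, res = coverage_res) > 0.5
    }
  }, TRUE)
  per <- tibble::tibble(
    obs = seq_len(nrow(observations)),
    year = if ("year" %in% names(observations))
      as.integer(observations$year) else NA_integer_,
    type = ifelse(vapply(observations$geometry, is_point_geom, TRUE),
                  "point", "polygon"),
    matched = matched)
  by_year <- dplyr::group_by(per, .data$year) |>
    dplyr::summarise(n = dplyr::n(),
                     matched_pct = 100 * mean(.data$matched),
                     bias_pct = 100 * mean(!.data$matched),
                     .groups = "drop")
  list(per_observation = per, by_year = by_year)
}

#' Plot-level count comparison (buffered plots, centroid counting)
#'
#' Each plot polygon is buffered by `buffer_m`; the predicted count is the
#' number of crown centroids inside the buffered plot. Observed counts come
#' either from a `count` column or from counting supplied census points
#' (filtered to `dbh_cm >= dbh_min_cm` when DBH is recorded). Overlapping
#' plots are each evaluated independently (with a warning: trees in the
#' overlap are counted for both).
#'
#' @param crowns a `crown_records` tibble.
#' @param plots a `vector_layer` of plot polygons with `count` and/or
#'   matching census points, plus optional `year`.
#' @param census optional `vector_layer` of dead-tree points with optional
#'   `dbh_cm` and a `plot` column naming the plot row.
#' @param buffer_m plot buffer distance, metres.
#' @param dbh_min_cm DBH filter applied to census points (NULL = keep all).
#' @return a [count_comparison()] with plot areas and years.
#' @export
compare_plots <- function(crowns, plots, census = NULL, buffer_m = 6,
                          dbh_min_cm = 40) {
  polys <- plots$geometry
  n <- length(polys)
  if (n > 1) {
    overlap <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (any(point_in_poly(polys[[j]][, 1], polys[[j]][, 2], polys[[i]])))
        overlap <- TRUE
    }
    if (overlap)
      warning("overlapping plots evaluated independently; ",
              "trees in the overlap are double-counted")
  }
  pred <- vapply(polys, function(p) {
    if (!nrow(crowns)) return(0L)
    sum(dist_to_geom(crowns$cx, crowns$cy, p) <= buffer_m)
  }, 0L)
  obs <- if ("count" %in% names(plots)) {
    as.numeric(plots$count)
  } else {
    stopifnot(!is.null(census))
    cen <- tibble::as_tibble(census)
    if (!is.null(dbh_min_cm) && "dbh_cm" %in% names(cen))
      cen <- dplyr::filter(cen, .data$dbh_cm >= dbh_min_cm)
    vapply(seq_len(n), function(i) {
      pts <- cen$geometry[cen$plot == i]
      if (!length(pts)) return(0)
      xs <- vapply(pts, `[`, 0, 1); ys <- vapply(pts, `[`, 0, 2)
      sum(point_in_poly(xs, ys, polys[[i]]))
    }, 0)
  }
  count_comparison(
    obs = obs, pred = pred, unit = seq_len(n),
    area_ha = vapply(polys, poly_area, 0) / 1e4,
    year = if ("year" %in% names(plots)) as.integer(plots$year)
    else NA_integer_)
}

#' Stratify a count comparison by fire perimeters
#'
#' Splits comparison units into fire / non-fire strata by whether the unit
#' location falls inside any fire perimeter, and reports bias and MAE per
#' stratum. The overall bias is the count-weighted combination of the
#' stratum biases (a bookkeeping identity, useful as a cross-check).
#'
#' @param comparison a [count_comparison()].
#' @param locations two-column matrix of unit locations (x, y).
#' @param fire_perimeters a `vector_layer` of fire polygons.
#' @return tibble `stratum`, `n`, `obs_total`, `mae`, `bias_pct`.
#' @export
stratified_bias <- function(comparison, locations, fire_perimeters) {
  in_fire <- rep(FALSE, nrow(comparison))
  for (g in fire_perimeters$geometry)
    in_fire <- in_fire | point_in_poly(locations[, 1], locations[, 2], g)
  strat <- function(sel, name) {
    if (!any(sel)) {
      return(tibble::tibble(stratum = name, n = 0L, obs_total = 0,
                            mae = NA_real_, bias_pct = NA_real_))
    }
    cc <- count_comparison(comparison$obs[sel], comparison$pred[sel])
    tibble::tibble(stratum = name, n = sum(sel),
                   obs_total = sum(cc$obs), mae = count_mae(cc),
                   bias_pct = count_bias(cc))
  }
  dplyr::bind_rows(strat(in_fire, "fire"),
                   strat(!in_fire, "non_fire"),
                   strat(rep(TRUE, nrow(comparison)), "overall"))
}
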