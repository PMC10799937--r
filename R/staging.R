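#' Mean crown colour with a one-pixel inner buffer
#'
#' Erodes each crown mask by one pixel (3x3 square structuring element) to
#' mitigate mixed edge pixels, then averages the R, G, B (and NIR) bands over
#' the remaining pixels. Crowns that erode to nothing fall back to the
#' un-eroded mask with a warning.
#'
#' @param labels integer label matrix or single-band `raster_tile`.
#' @param image 4-band `raster_tile` aligned to `labels`.
#' @return tibble with `id`, `R`, `G`, `B`, `N`, `n_px_used`,
#'   `eroded_empty`.
#' @export
mean_crown_rgb <- function(labels, image) {
  lab <- if (inherits(labels, "raster_tile")) labels$pixels[, , 1] else labels
  storage.mode(lab) <- "integer"
  stopifnot(all(dim(lab) == dim(image$pixels)[1:2]))
  kern <- matrix(1, 3, 3)
  ids <- sort(unique(lab[lab > 0L]))
  fallback <- 0L
  rows <- lapply(ids, function(id) {
    m <- (lab == id) * 1
    er <- EBImage::erode(m, kern)
    empty <- !any(er > 0)
    use <- if (empty) m > 0 else er > 0
    if (empty) fallback <<- fallback + 1L
    idx <- which(use)
    n <- length(lab)
    tibble::tibble(
      id = id,
      R = mean(image$pixels[idx]), G = mean(image$pixels[idx + n]),
      B = mean(image$pixels[idx + 2L * n]),
      N = mean(image$pixels[idx + 3L * n]),
      n_px_used = length(idx), eroded_empty = empty)
  })
  if (fallback > 0L)
    warning(fallback, " crown(s) eroded to empty; using un-eroded mask")
  if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    id = integer(), R = numeric(), G = numeric(), B = numeric(),
    N = numeric(), n_px_used = integer(), eroded_empty = logical())
}

#' HSV stage scores for mean crown colours
#'
#' Converts mean RGB (0-255) to hexcone HSV with H, S, V in [0, 1] and
#' computes the four class scores. The hue terms are
#' `H_g = 1 - |H - 1/3| / (1/6)` and `H_r = (1/2 - H) / (1/6) - 2`; hues
#' above 5/6 (reds at the top of the hue circle) are wrapped to `H - 1`
#' before computing `H_r`. Each score uses the bounded exponential form
#' `(C^x - 1) / (C - 1)` with constants `C = (Cg, Cr, Cy, Cb) =
#' (5, 5, 1e7, 1e4)`: X_green from H_g (0 when H_g < 0), X_brown from H_r
#' (0 when H_r < 0, clamped at 1 when H_r > 1), X_grey from `1 - S`,
#' X_background from `1 - V`. When S = 0 the hue is undefined and both
#' hue-based scores are set to 0; when V = 0 the saturation is undefined
#' as well and X_grey is set to 0 (black pixels are pure background).
#' `literal_exponent = TRUE` switches the two hue scores to the alternative
#' `C^(x-1) / (C-1)` reading.
#'
#' @param rgb data frame with columns `R`, `G`, `B` in 0..255 (extra columns
#'   are carried through), or a length-3 numeric vector.
#' @param constants named numeric `c(Cg, Cr, Cy, Cb)`.
#' @param literal_exponent use the `C^(x-1)` numerator variant.
#' @return input tibble plus `H`, `S`, `V`, `Hg`, `Hr`, `X_green`,
#'   `X_brown`, `X_grey`, `X_background`.
#' @export
stage_scores <- function(rgb,
                         constants = c(Cg = 5, Cr = 5, Cy = 1e7, Cb = 1e4),
                         literal_exponent = FALSE) {
  if (is.numeric(rgb) && length(rgb) == 3)
    rgb <- tibble::tibble(R = rgb[1], G = rgb[2], B = rgb[3])
  rgb <- tibble::as_tibble(rgb)
  stopifnot(all(c("R", "G", "B") %in% names(rgb)))
  hsv <- grDevices::rgb2hsv(t(as.matrix(rgb[c("R", "G", "B")])),
                            maxColorValue = 255)
  H <- unname(hsv[1, ]); S <- unname(hsv[2, ]); V <- unname(hsv[3, ])
  Hw <- ifelse(H > 5 / 6, H - 1, H)      # red hues wrap across H = 0
  Hg <- 1 - abs(H - 1 / 3) / (1 / 6)
  Hr <- (1 / 2 - Hw) / (1 / 6) - 2
  Cg <- constants[["Cg"]]; Cr <- constants[["Cr"]]
  Cy <- constants[["Cy"]]; Cb <- constants[["Cb"]]
  fx <- if (literal_exponent) {
    function(C, x) C^(x - 1) / (C - 1)
  } else {
    function(C, x) (C^x - 1) / (C - 1)
  }
  Xg <- ifelse(Hg >= 0, fx(Cg, pmin(Hg, 1)), 0)
  Xb <- ifelse(Hr >= 0, fx(Cr, pmin(Hr, 1)), 0)
  Xg[S == 0] <- 0
  Xb[S == 0] <- 0
  Xgrey <- fx(Cy, 1 - S)
  Xgrey[V == 0] <- 0      # saturation undefined on black pixels
  dplyr::bind_cols(rgb, tibble::tibble(
    H = H, S = S, V = V, Hg = Hg, Hr = Hr,
    X_green = pmin(1, pmax(0, Xg)),
    X_brown = pmin(1, pmax(0, Xb)),
    X_grey = Xgrey,
    X_background = fx(Cb, 1 - V)))
}

stage_class_order <- c("grey", "brown", "green", "background")

#' Classify stage scores by argmax
#'
#' The class with the maximal score wins; exact ties resolve in the fixed
#' priority grey > brown > green > background (conservative with respect to
#' recent-mortality claims). Crowns classified green or background are kept
#' as records but flagged as non-dead-stage for QA.
#'
#' @param scores tibble from [stage_scores()].
#' @return `scores` plus a `stage` factor (brown/grey/green/background).
#' @export
classify_stage <- function(scores) {
  X <- as.matrix(scores[c("X_grey", "X_brown", "X_green", "X_background")])
  win <- stage_class_order[apply(X, 1, which.max)]
  dplyr::mutate(scores, stage = factor(win, levels = c(
    "brown", "grey", "green", "background")))
}

#' Stage every crown in a record table from the source image
#'
#' Convenience wrapper: one-pixel inner buffer, mean colour, HSV scores,
#' argmax classification; the `stage` column of the crown records is
#' replaced and the scores attached.
#'
#' @param crowns a `crown_records` tibble (from [extract_crowns()]).
#' @param labels label matrix or `raster_tile` the crowns came from.
#' @param image 4-band `raster_tile`.
#' @param cfg a [run_config()] (staging constants and exponent variant).
#' @return `crowns` with `stage` filled in and score columns appended.
#' @export
stage_crowns <- function(crowns, labels, image, cfg = run_config()) {
  if (!nrow(crowns)) return(crowns)
  cols <- mean_crown_rgb(labels, image)
  sc <- classify_stage(stage_scores(
    cols, constants = cfg$staging_constants,
    literal_exponent = cfg$literal_exponent))
  out <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(crowns), -"stage"),
    dplyr::select(sc, "id", "stage", dplyr::starts_with("X_"),
                  "H", "S", "V"),
    by = "id")
  out$stage <- as.character(out$stage)
  structure(out, crs = attr(crowns, "crs"), px = attr(crowns, "px"),
            class = class(crowns))
}

#' Validate brown-stage counts against survey polygons
#'
#' Overlays survey polygons (e.g. sketch-mapped damage areas where
#' brown-stage trees were identified) on a gridded brown-stage count layer,
#' sums the counts per polygon, and reports the fraction of polygons with no
#' brown-stage tree (a false-negative proxy). Polygons smaller than
#' `min_area_ha` are discarded so that each retained polygon covers at least
#' one grid cell.
#'
#' @param brown_counts tibble with `row`, `col`, `value` (brown counts per
#'   cell) as produced against `spec`.
#' @param spec the `grid_spec` of the count layer.
#' @param survey_polygons a `vector_layer` of polygons with a `year` column.
#' @param min_area_ha minimum polygon area in hectares.
#' @return list with `per_polygon` tibble (`polygon`, `year`, `area_ha`,
#'   `brown_total`, `false_negative`) and scalar `false_negative_rate`.
#' @export
validate_stage_by_polygons <- function(brown_counts, spec, survey_polygons,
                                       min_area_ha = 1) {
  cs <- spec$cell_size
  centres <- expand.grid(col = seq_len(spec$ncol), row = seq_len(spec$nrow))
  centres$x <- spec$x0 + (centres$col - 0.5) * cs
  centres$y <- spec$y0 - (centres$row - 0.5) * cs
  counts <- dplyr::left_join(centres, brown_counts, by = c("row", "col"))
  counts$value[is.na(counts$value)] <- 0
  rows <- lapply(seq_len(nrow(survey_polygons)), function(i) {
    g <- survey_polygons$geometry[[i]]
    area_ha <- poly_area(g) / 1e4
    if (area_ha < min_area_ha) return(NULL)
    inside <- point_in_poly(counts$x, counts$y, g)
    tot <- sum(counts$value[inside])
    tibble::tibble(polygon = i,
                   year = if ("year" %in% names(survey_polygons))
                     survey_polygons$year[i] else NA_integer_,
                   area_ha = area_ha, brown_total = tot,
                   false_negative = tot == 0)
  })
  per <- dplyr::bind_rows(rows)
  list(per_polygon = per,
       false_negative_rate = if (nrow(per)) mean(per$false_negative) else NA_real_)
}
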