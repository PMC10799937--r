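#' Extract crown records from an instance label raster
#'
#' Per instance: interior holes are filled, the filled region is polygonised
#' (0.5-isoline of the mask), and geometry is summarised as filled area in
#' square metres, centroid in map coordinates, and the moment-equivalent
#' ellipse. Semi-axes come from the second-order central moments
#' (`a = 2*sqrt(lambda1)`, `b = 2*sqrt(lambda2)`, the exact relation for a
#' uniform ellipse); the eccentricity is `e = c/a = sqrt(1 - (b/a)^2)` with
#' `c` the focal distance. Degenerate single-pixel regions get
#' `a = b = px/2`, `e = 0`.
#'
#' @param labels integer label matrix or single-band `raster_tile`.
#' @param image optional 4-band `raster_tile` recorded as the source tile.
#' @param source_tile identifier stored with each record.
#' @return a `crown_records` tibble: `id`, `n_px`, `area_m2`, `cx`, `cy`,
#'   `a`, `b`, `ecc`, `stage` (initially "unclassified"), `agents`
#'   (list-column), `polygon` (list-column of rings), `source_tile`.
#' @export
extract_crowns <- function(labels, image = NULL, source_tile = "tile") {
  if (inherits(labels, "raster_tile")) {
    geo <- labels
    lab <- labels$pixels[, , 1]
  } else {
    lab <- labels
    geo <- raster_tile(lab)
  }
  storage.mode(lab) <- "integer"
  px <- geo$px
  lab <- fill_label_holes(lab)
  ids <- sort(unique(lab[lab > 0L]))
  n_degenerate <- 0L
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    ctr <- pixel_centres(geo, idx[, 1], idx[, 2])
    n_px <- nrow(idx)
    cx <- mean(ctr[, 1]); cy <- mean(ctr[, 2])
    if (n_px == 1L) {
      n_degenerate <<- n_degenerate + 1L
      a <- px / 2; b <- px / 2; ecc <- 0
    } else {
      dx <- ctr[, 1] - cx; dy <- ctr[, 2] - cy
      mu20 <- mean(dx * dx); mu02 <- mean(dy * dy); mu11 <- mean(dx * dy)
      tr <- mu20 + mu02
      det <- mu20 * mu02 - mu11 * mu11
      disc <- sqrt(max(0, tr * tr / 4 - det))
      l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
      a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
      if (b <= px / 4) b <- px / 4  # thin 1-px-wide shapes: avoid e = 1
      ecc <- sqrt(max(0, 1 - (b / a)^2))
    }
    tibble::tibble(
      id = id, n_px = n_px, area_m2 = n_px * px * px,
      cx = cx, cy = cy, a = a, b = b, ecc = ecc,
      stage = "unclassified", agents = list(character(0)),
      polygon = list(trace_outline(lab == id, geo)),
      source_tile = source_tile)
  })
  if (n_degenerate > 0L)
    message(n_degenerate, " single-pixel crown(s): a = b = half pixel, e = 0")
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    id = integer(), n_px = integer(), area_m2 = numeric(), cx = numeric(),
    cy = numeric(), a = numeric(), b = numeric(), ecc = numeric(),
    stage = character(), agents = list(), polygon = list(),
    source_tile = character())
  structure(out, crs = geo$crs, px = px,
            class = c("crown_records", class(tibble::tibble())))
}

# Fill interior holes of every labelled object, preserving labels.
fill_label_holes <- function(lab) {
  filled <- EBImage::fillHull(lab)
  storage.mode(filled) <- "integer"
  filled
}

# Outer 0.5-isoline of a logical mask, in map coordinates (largest ring).
trace_outline <- function(mask, geo) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask * 1
  # contourLines treats rows of z as x; orient so x = easting, y = northing
  xs <- geo$xmin + ((0:(W + 1L)) - 0.5) * geo$px   # column centres (padded)
  ys <- geo$ymax - ((0:(H + 1L)) - 0.5) * geo$px   # row centres (padded)
  cl <- grDevices::contourLines(x = xs, y = rev(ys), z = t(pad)[, (H + 2L):1],
                                levels = 0.5)
  if (!length(cl)) {
    idx <- which(mask, arr.ind = TRUE)
    ctr <- pixel_centres(geo, idx[1, 1], idx[1, 2])
    h <- geo$px / 2
    return(rect_polygon(ctr[1] - h, ctr[2] - h, ctr[1] + h, ctr[2] + h))
  }
  rings <- lapply(cl, function(li) repair_geometry(cbind(li$x, li$y)))
  areas <- vapply(rings, function(r)
    if (nrow(r) >= 4) poly_area(r) else 0, 0)
  rings[[which.max(areas)]]
}

#' Median crown eccentricity on a coarse grid, with a distortion flag
#'
#' Aggregates per-crown eccentricity to grid cells (centroid assignment),
#' keeping only crowns larger than `min_px` pixels (at 0.6 m GSD, 50 px is
#' 18 m^2). Cells whose median exceeds `flag_threshold` are flagged as
#' likely affected by off-nadir geometric distortion; area-related products
#' should be used cautiously there.
#'
#' @param crowns a `crown_records` tibble.
#' @param spec a `grid_spec` (conventionally 500 m cells).
#' @param min_px minimum crown size in pixels (strictly greater-than).
#' @param flag_threshold median eccentricity above which a cell is flagged.
#' @return tibble with `row`, `col`, `value` (median eccentricity),
#'   `n_crowns`, `flagged`.
#' @export
eccentricity_grid <- function(crowns, spec, min_px = 50L,
                              flag_threshold = 0.8) {
  big <- dplyr::filter(tibble::as_tibble(crowns), .data$n_px > min_px)
  if (!nrow(big)) {
    return(tibble::tibble(row = integer(), col = integer(), value = numeric(),
                          n_crowns = integer(), flagged = logical()))
  }
  cells <- grid_cell(spec, big$cx, big$cy)
  dplyr::bind_cols(big, cells) |>
    dplyr::filter(!is.na(.data$row)) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(value = stats::median(.data$ecc),
                     n_crowns = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(flagged = .data$value > flag_threshold)
}
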