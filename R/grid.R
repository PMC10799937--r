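#' Regular analysis grid
#'
#' Axis-aligned grid anchored at a top-left origin `(x0, y0)` with square
#' cells of `cell_size` metres. Cells are half-open: a point on a shared edge
#' belongs to exactly one cell. Row 1 is the northernmost row.
#'
#' @param x0,y0 map coordinates of the grid's top-left corner.
#' @param cell_size cell side length in metres (30/100/240/500 are the usual
#'   choices; any positive value is accepted).
#' @param ncol,nrow grid extent in cells.
#' @param crs projected CRS identifier.
#' @return a `grid_spec`.
#' @export
grid_spec <- function(x0, y0, cell_size, ncol, nrow, crs = "EPSG:32611") {
  stopifnot(cell_size > 0, ncol >= 1, nrow >= 1)
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size,
                 ncol = as.integer(ncol), nrow = as.integer(nrow), crs = crs),
            class = "grid_spec")
}

#' Grid spec covering a raster tile
#' @param tile a `raster_tile`.
#' @param cell_size cell side length in metres.
#' @return a `grid_spec` anchored at the tile's top-left corner.
#' @export
grid_for_tile <- function(tile, cell_size) {
  ext <- rt_extent(tile)
  grid_spec(ext["xmin"], ext["ymax"], cell_size,
            ncol = ceiling((ext["xmax"] - ext["xmin"]) / cell_size),
            nrow = ceiling((ext["ymax"] - ext["ymin"]) / cell_size),
            crs = tile$crs)
}

#' Assign map points to grid cells
#' @param spec a `grid_spec`.
#' @param x,y map coordinates.
#' @return tibble with `row`, `col` (NA outside the grid).
#' @export
grid_cell <- function(spec, x, y) {
  col <- as.integer(floor((x - spec$x0) / spec$cell_size)) + 1L
  row <- as.integer(floor((spec$y0 - y) / spec$cell_size)) + 1L
  bad <- col < 1L | col > spec$ncol | row < 1L | row > spec$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  tibble::tibble(row = row, col = col)
}

#' Materialise per-cell values as a single-band raster
#'
#' @param values a data frame with `row`, `col`, `value` (sparse mapping; at
#'   most one value per cell).
#' @param spec a `grid_spec`.
#' @param nodata sentinel for cells without a value.
#' @param range optional c(lo, hi); values outside warn but are kept.
#' @param metric metric name recorded in the raster tags.
#' @param bias_corrected flag recorded in the raster tags.
#' @return a single-band `raster_tile` with `px = cell_size`.
#' @export
rasterize_grid_metric <- function(values, spec, nodata = -9999,
                                  range = NULL, metric = "metric",
                                  bias_corrected = FALSE) {
  m <- matrix(nodata, spec$nrow, spec$ncol)
  if (nrow(values)) {
    stopifnot(all(c("row", "col", "value") %in% names(values)))
    if (anyDuplicated(values[c("row", "col")]))
      stop("duplicate cell in grid metric values")
    if (!is.null(range)) {
      out <- stats::na.omit(values$value)
      if (any(out < range[1] | out > range[2]))
        warning("grid metric values outside declared range [",
                range[1], ", ", range[2], "] kept as-is")
    }
    ok <- !is.na(values$row) & !is.na(values$col) & !is.na(values$value)
    m[cbind(values$row[ok], values$col[ok])] <- values$value[ok]
  }
  raster_tile(m, xmin = spec$x0, ymax = spec$y0, px = spec$cell_size,
              crs = spec$crs, nodata = nodata,
              tags = list(metric = metric, bias_corrected = bias_corrected))
}

#' Turn a single-band grid raster back into a sparse cell table
#' @param layer single-band `raster_tile`.
#' @return tibble with `row`, `col`, `value` for non-nodata cells.
#' @export
grid_values <- function(layer) {
  m <- layer$pixels[, , 1]
  idx <- which(if (is.null(layer$nodata)) !is.na(m) else m != layer$nodata,
               arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2], value = m[idx])
}
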