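#' Georeferenced raster tile
#'
#' Light container for a north-up, square-pixel raster in a projected CRS
#' (map units metres). Pixels are stored as a numeric array `H x W x nbands`
#' (row 1 = northernmost row, column 1 = westernmost column); single-band
#' rasters may be plain matrices. The geotransform is the top-left corner
#' `(xmin, ymax)` plus the pixel size `px` in metres.
#'
#' @param pixels numeric array `H x W x nbands` or matrix `H x W`.
#' @param xmin,ymax map coordinates of the top-left corner of pixel (1, 1).
#' @param px pixel size in metres (> 0).
#' @param crs projected CRS identifier (free-form string, e.g. "EPSG:32611").
#' @param nodata optional nodata sentinel value.
#' @param tags named list of scalar metadata written to the sidecar on save.
#' @return an object of class `raster_tile`.
#' @export
raster_tile <- function(pixels, xmin = 0, ymax = NULL, px = 0.6,
                        crs = "EPSG:32611", nodata = NULL, tags = list()) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  stopifnot(length(dim(pixels)) == 3L, px > 0, is.character(crs), nzchar(crs))
  if (is.null(ymax)) ymax <- nrow(pixels) * px
  structure(
    list(pixels = pixels, xmin = xmin, ymax = ymax, px = px,
         crs = crs, nodata = nodata, tags = tags),
    class = "raster_tile"
  )
}

#' @export
print.raster_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_tile> %d x %d px, %d band(s), px = %g m, crs = %s\n",
              d[1], d[2], d[3], x$px, x$crs))
  cat(sprintf("  origin (xmin, ymax) = (%g, %g)\n", x$xmin, x$ymax))
  invisible(x)
}

#' @export
dim.raster_tile <- function(x) dim(x$pixels)

rt_nrow <- function(tile) dim(tile$pixels)[1]
rt_ncol <- function(tile) dim(tile$pixels)[2]
rt_nbands <- function(tile) dim(tile$pixels)[3]

#' Map extent of a tile as c(xmin, ymin, xmax, ymax)
#' @param tile a `raster_tile`.
#' @return numeric length-4 vector.
#' @export
rt_extent <- function(tile) {
  c(xmin = tile$xmin, ymin = tile$ymax - rt_nrow(tile) * tile$px,
    xmax = tile$xmin + rt_ncol(tile) * tile$px, ymax = tile$ymax)
}

#' Map coordinates of pixel centres
#'
#' @param tile a `raster_tile`.
#' @param rows,cols integer pixel indices (1-based, row 1 at top).
#' @return two-column matrix of (x, y) centres.
#' @export
pixel_centres <- function(tile, rows, cols) {
  cbind(x = tile$xmin + (cols - 0.5) * tile$px,
        y = tile$ymax - (rows - 0.5) * tile$px)
}

#' Pixel indices containing map coordinates (half-open cells)
#' @param tile a `raster_tile`.
#' @param x,y map coordinates.
#' @return two-column integer matrix (row, col); coordinates outside the
#'   extent give indices outside `1..nrow/ncol`.
#' @export
map_to_pixel <- function(tile, x, y) {
  cbind(row = as.integer(floor((tile$ymax - y) / tile$px)) + 1L,
        col = as.integer(floor((x - tile$xmin) / tile$px)) + 1L)
}

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write a raster tile to disk
#'
#' Pixels go to a TIFF file; the geotransform, CRS, nodata value and tags go
#' to a JSON sidecar `<path>.aux.json`. Integer-valued bands round-trip
#' bit-exactly (16-bit storage); other values are stored as 32-bit floats.
#'
#' @param tile a `raster_tile`.
#' @param path output path (conventionally `.tif`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(tile, path) {
  px <- tile$pixels
  storage.mode(px) <- "numeric"
  mx <- suppressWarnings(max(abs(px), na.rm = TRUE))
  if (!is.finite(mx)) mx <- 0
  int_ok <- mx <= 65535 && isTRUE(all(px == round(px) & px >= 0, na.rm = TRUE))
  float_range <- NULL
  if (int_ok) {
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  } else {
    # normalise into [0, 1] for float TIFF storage; range goes to the sidecar
    lo <- min(px, na.rm = TRUE); hi <- max(px, na.rm = TRUE)
    if (hi == lo) hi <- lo + 1
    tiff::writeTIFF((px - lo) / (hi - lo), path, bits.per.sample = 32L)
    float_range <- c(lo, hi)
  }
  meta <- list(xmin = tile$xmin, ymax = tile$ymax, px = tile$px,
               crs = tile$crs, nodata = tile$nodata,
               integer_scaled = int_ok, float_range = float_range,
               nbands = rt_nbands(tile), tags = tile$tags)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a raster tile from disk
#'
#' Reads a TIFF written by [write_raster()] (or any plain TIFF with a JSON
#' sidecar describing its georeferencing). Inputs with exactly 3 bands get a
#' synthesised all-zero NIR band with a warning; a missing CRS is an error.
#'
#' @param path file path.
#' @param expect_bands if not `NULL`, minimum number of bands required.
#' @return a `raster_tile`.
#' @export
read_raster <- function(path, expect_bands = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing georeferencing sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$crs) || !nzchar(meta$crs)) stop("raster has no CRS: ", path)
  px <- tryCatch(
    withCallingHandlers(
      tiff::readTIFF(path),
      warning = function(w) {
        # benign libtiff chatter about >3 channels lacking colour tags
        if (grepl("ExtraSamples|Photometric", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e)
      stop("unreadable raster file: ", path, " (", conditionMessage(e), ")"))
  if (is.matrix(px)) px <- array(px, dim = c(dim(px), 1L))
  if (isTRUE(meta$integer_scaled)) {
    px <- round(px * 65535)
  } else if (!is.null(meta$float_range)) {
    rng <- as.numeric(meta$float_range)
    px <- px * (rng[2] - rng[1]) + rng[1]
  }
  if (!is.null(expect_bands) && dim(px)[3] < expect_bands)
    stop("expected >= ", expect_bands, " bands, found ", dim(px)[3])
  if (dim(px)[3] == 3L) {
    warning("3-band raster: synthesising an all-zero NIR band")
    px <- array(c(px, array(0, dim = c(dim(px)[1:2], 1L))),
                dim = c(dim(px)[1:2], 4L))
  }
  tags <- meta$tags
  if (is.null(tags)) tags <- list()
  raster_tile(px, xmin = as.numeric(meta$xmin), ymax = as.numeric(meta$ymax),
              px = as.numeric(meta$px), crs = meta$crs,
              nodata = if (!is.null(meta$nodata)) as.numeric(meta$nodata),
              tags = as.list(tags))
}

#' Split a raster into patches
#'
#' Patches of `patch_size` pixels with `overlap` shared pixels between
#' neighbours, covering the input completely; the final row/column of patches
#' is shifted inwards so that no patch exceeds the raster. Rasters smaller
#' than `patch_size` yield a single zero-padded patch (padding carries the
#' nodata value, or 0).
#'
#' @param tile a `raster_tile`.
#' @param patch_size patch side length in pixels.
#' @param overlap shared pixels between adjacent patches (`< patch_size`).
#' @return a list of `raster_tile` patches; each carries tags `row_off` and
#'   `col_off` (0-based offsets into the parent).
#' @export
tile_raster <- function(tile, patch_size = 256L, overlap = 0L) {
  stopifnot(patch_size > overlap, overlap >= 0)
  H <- rt_nrow(tile); W <- rt_ncol(tile); nb <- rt_nbands(tile)
  if (H < patch_size || W < patch_size) {
    fill <- if (!is.null(tile$nodata)) tile$nodata else 0
    pad <- array(fill, dim = c(max(H, patch_size), max(W, patch_size), nb))
    pad[seq_len(H), seq_len(W), ] <- tile$pixels
    message("raster smaller than patch size; emitting one padded patch")
    out <- raster_tile(pad, tile$xmin, tile$ymax, tile$px, tile$crs,
                       tile$nodata, c(tile$tags, row_off = 0L, col_off = 0L))
    return(list(out))
  }
  step <- patch_size - overlap
  offs <- function(total) {
    o <- seq(0L, max(total - patch_size, 0L), by = step)
    if (o[length(o)] + patch_size < total) o <- c(o, total - patch_size)
    as.integer(o)
  }
  out <- list()
  for (ro in offs(H)) for (co in offs(W)) {
    sub <- tile$pixels[(ro + 1L):(ro + patch_size),
                       (co + 1L):(co + patch_size), , drop = FALSE]
    out[[length(out) + 1L]] <- raster_tile(
      sub, xmin = tile$xmin + co * tile$px, ymax = tile$ymax - ro * tile$px,
      px = tile$px, crs = tile$crs, nodata = tile$nodata,
      tags = c(tile$tags, list(row_off = ro, col_off = co)))
  }
  out
}
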