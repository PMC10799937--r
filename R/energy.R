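#' Ordinal energy map
#'
#' Integer raster of per-pixel energy levels `0..K` (0 = background) encoding
#' quantised distance to the nearest instance boundary: level 1 is the
#' boundary ring, level K the innermost core. Within an instance the level-j
#' super-level sets are spatially nested, which is what the ordinal
#' classification head of the network predicts.
#'
#' @param levels integer matrix of levels in `[0, K]`.
#' @param K number of energy levels.
#' @param xmin,ymax,px,crs georeferencing (as in [raster_tile()]).
#' @return an `energy_map`.
#' @export
energy_map <- function(levels, K, xmin = 0, ymax = NULL, px = 0.6,
                       crs = "EPSG:32611") {
  storage.mode(levels) <- "integer"
  stopifnot(K >= 2, all(levels >= 0L & levels <= K))
  if (is.null(ymax)) ymax <- nrow(levels) * px
  structure(list(levels = levels, K = as.integer(K), xmin = xmin,
                 ymax = ymax, px = px, crs = crs),
            class = "energy_map")
}

#' @export
print.energy_map <- function(x, ...) {
  cat(sprintf("<energy_map> %d x %d px, K = %d, occupied = %.1f%%\n",
              nrow(x$levels), ncol(x$levels), x$K,
              100 * mean(x$levels > 0)))
  invisible(x)
}

#' Encode instance labels as ordinal energy levels
#'
#' Per instance, the Euclidean distance of each pixel to the instance
#' boundary is computed, normalised, and quantised into K bins: the boundary
#' ring gets level 1, the innermost pixels level K. With
#' `normalisation = "instance"` the distance is scaled by that instance's
#' maximum (small and large crowns both reach level K); `"absolute"`
#' quantises raw pixel distance at one level per pixel, capped at K.
#' Single-pixel instances get level K directly.
#'
#' @param instances integer label matrix or single-band `raster_tile`
#'   (0 = background).
#' @param K number of energy levels (>= 2).
#' @param normalisation `"instance"` or `"absolute"`.
#' @param quiet suppress the degenerate-instance message.
#' @return an `energy_map` aligned to the input.
#' @export
instances_to_energy <- function(instances, K = 5L,
                                normalisation = c("instance", "absolute"),
                                quiet = FALSE) {
  normalisation <- match.arg(normalisation)
  geo <- list(xmin = 0, ymax = NULL, px = 0.6, crs = "EPSG:32611")
  if (inherits(instances, "raster_tile")) {
    geo <- instances[c("xmin", "ymax", "px", "crs")]
    instances <- instances$pixels[, , 1]
  }
  lab <- instances
  storage.mode(lab) <- "integer"
  stopifnot(K >= 2, all(lab >= 0L))
  lev <- matrix(0L, nrow(lab), ncol(lab))
  ids <- sort(unique(lab[lab > 0L]))
  n_degenerate <- 0L
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) == 1L) {
      lev[idx] <- K
      n_degenerate <- n_degenerate + 1L
      next
    }
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    m <- matrix(0, r1 - r0 + 3L, c1 - c0 + 3L)  # 1-px background pad
    m[cbind(idx[, 1] - r0 + 2L, idx[, 2] - c0 + 2L)] <- 1
    d <- EBImage::distmap(m, metric = "euclidean")
    d <- d[cbind(idx[, 1] - r0 + 2L, idx[, 2] - c0 + 2L)]
    lv <- if (normalisation == "instance") {
      dmax <- max(d)
      pmin(K, pmax(1L, as.integer(ceiling(K * d / dmax))))
    } else {
      pmin(K, pmax(1L, as.integer(ceiling(d))))
    }
    lev[idx] <- lv
  }
  if (n_degenerate > 0L && !quiet)
    message(n_degenerate, " single-pixel instance(s) assigned level K directly")
  energy_map(lev, K, xmin = geo$xmin, ymax = geo$ymax, px = geo$px,
             crs = geo$crs)
}

#' Expand an energy map into K nested binary masks
#'
#' `mask_j = 1(level >= j)`; the masks are monotone (`mask_j` inside
#' `mask_{j-1}`) and the inverse operation (count of true masks per pixel)
#' reproduces the level raster exactly.
#'
#' @param e an `energy_map`.
#' @return numeric array `H x W x K` of 0/1 masks.
#' @export
energy_to_ordinal <- function(e) {
  K <- e$K
  out <- array(0, dim = c(nrow(e$levels), ncol(e$levels), K))
  for (j in seq_len(K)) out[, , j] <- (e$levels >= j) * 1
  out
}

#' Collapse nested ordinal masks back to an energy map
#' @param masks array `H x W x K` of 0/1 nested masks.
#' @param ... georeferencing passed to [energy_map()].
#' @return an `energy_map`.
#' @export
ordinal_to_energy <- function(masks, ...) {
  K <- dim(masks)[3]
  lev <- matrix(0L, dim(masks)[1], dim(masks)[2])
  for (j in seq_len(K)) lev <- lev + (masks[, , j] > 0.5)
  energy_map(lev, K, ...)
}

#' Enforce ordinal consistency on per-level probability maps
#'
#' The per-level sigmoid head does not guarantee nesting; the cumulative
#' product `q_j = prod_{i<=j} p_i` does (a missing low level blocks all
#' higher levels). The decoded level is the largest j with
#' `q_j >= threshold`, or 0.
#'
#' @param probabilities array `H x W x K` of per-level probabilities.
#' @param threshold presence threshold in (0, 1).
#' @param ... georeferencing passed to [energy_map()].
#' @return an `energy_map` satisfying ordinal nesting by construction.
#' @export
monotone_enforce <- function(probabilities, threshold = 0.5, ...) {
  K <- dim(probabilities)[3]
  q <- matrix(1, dim(probabilities)[1], dim(probabilities)[2])
  lev <- matrix(0L, nrow(q), ncol(q))
  for (j in seq_len(K)) {
    q <- q * probabilities[, , j]
    lev <- lev + (q >= threshold)   # q is non-increasing in j
  }
  energy_map(lev, K, ...)
}
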