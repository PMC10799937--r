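#' Connected-component labelling
#'
#' Synchronous minimum-label propagation (ties to the smallest label);
#' `connectivity = 2` (the default) means 8-neighbour (second-order)
#' connectivity, `1` means 4-neighbour.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 1 (edge-adjacent) or 2 (edge- or corner-adjacent).
#' @return integer matrix of labels dense from 1 (0 = background), numbered
#'   by first occurrence in column-major order.
#' @export
label_components <- function(mask, connectivity = 2L) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  cc_label(m, as.integer(connectivity))
}

#' Separate an energy map into instances by marker-based watershed
#'
#' Markers are the connected components of the top non-empty energy level
#' within each basin (8-connectivity); the flood then descends the energy
#' levels, at each level repeatedly growing every marker into unlabelled
#' pixels of at least that level until no pixel changes. Touching crowns
#' split at the energy valley between their level-K cores. Components
#' smaller than `min_pixels` are removed and labels re-densified.
#'
#' @param e an `energy_map`.
#' @param min_pixels minimum instance size in pixels (smaller components are
#'   dropped as speckle).
#' @return single-band integer `raster_tile` of instance labels dense from 1
#'   (tag `K` records the energy depth used).
#' @export
watershed_instances <- function(e, min_pixels = 8L) {
  lev <- e$levels
  K <- e$K
  mask <- lev >= 1L
  if (!any(mask)) {
    return(raster_tile(matrix(0L, nrow(lev), ncol(lev)), e$xmin, e$ymax,
                       e$px, e$crs, tags = list(K = K)))
  }
  comp <- label_components(mask, connectivity = 2L)
  tops <- vapply(split(lev[mask], comp[mask]), max, 0L)
  top_of <- matrix(0L, nrow(lev), ncol(lev))
  top_of[mask] <- tops[comp[mask]]    # components are dense from 1
  seed_mask <- mask & lev == top_of
  seeds <- label_components(seed_mask, connectivity = 2L)
  labels <- ws_flood(matrix(as.integer(lev), nrow(lev)), seeds, K)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_pixels)
  out <- matrix(0L, nrow(lev), ncol(lev))
  pos <- labels > 0L & labels %in% keep
  out[pos] <- match(labels[pos], keep)
  raster_tile(out, e$xmin, e$ymax, e$px, e$crs,
              tags = list(K = K, n_removed = length(sizes) - length(keep)))
}
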