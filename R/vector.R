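#' Vector layer
#'
#' A tibble of features with a `geometry` list-column plus a CRS attribute.
#' Geometries are either single points (length-2 numeric vectors) or simple
#' polygons (closed rings as two-column `(x, y)` matrices, exterior only).
#' This deliberately covers what the pipeline needs: crown outlines, survey
#' points, plot and damage-agent polygons.
#'
#' @param features a data frame with a `geometry` list-column; other columns
#'   are feature attributes.
#' @param crs projected CRS identifier.
#' @return a `vector_layer` (tibble subclass).
#' @export
vector_layer <- function(features = tibble::tibble(geometry = list()),
                         crs = "EPSG:32611") {
  features <- tibble::as_tibble(features)
  stopifnot("geometry" %in% names(features))
  features$geometry <- lapply(features$geometry, repair_geometry)
  structure(features, crs = crs,
            class = c("vector_layer", class(tibble::tibble())))
}

#' CRS of a vector layer
#' @param layer a `vector_layer`.
#' @return the CRS identifier string.
#' @export
vl_crs <- function(layer) attr(layer, "crs")

# Close unclosed rings, drop duplicated consecutive vertices; points pass
# through. Self-intersection repair beyond ring closure is out of scope for
# the simple shapes handled here.
repair_geometry <- function(g) {
  if (is.null(g)) return(g)
  if (!is.matrix(g)) return(as.numeric(g))
  if (nrow(g) >= 2) {
    keep <- c(TRUE, rowSums(abs(diff(g))) > 0)
    g <- g[keep, , drop = FALSE]
  }
  if (nrow(g) >= 3 && any(g[1, ] != g[nrow(g), ])) g <- rbind(g, g[1, ])
  g
}

is_point_geom <- function(g) !is.matrix(g)

#' Write a vector layer as GeoJSON
#' @param layer a `vector_layer`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vector <- function(layer, path) {
  attrs <- layer[setdiff(names(layer), "geometry")]
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    g <- layer$geometry[[i]]
    geom <- if (is_point_geom(g)) {
      list(type = "Point", coordinates = as.numeric(g))
    } else {
      list(type = "Polygon", coordinates = list(unname(
        lapply(seq_len(nrow(g)), function(j) as.numeric(g[j, ])))))
    }
    props <- lapply(attrs[i, , drop = FALSE], function(v) {
      v <- v[[1]]
      if (is.list(v)) v <- unlist(v)
      if (length(v) != 1) v <- paste(v, collapse = ";")
      v
    })
    list(type = "Feature", geometry = geom, properties = props)
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = vl_crs(layer))),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a GeoJSON vector layer
#' @param path file path.
#' @return a `vector_layer`.
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path)
  obj <- jsonlite::read_json(path)
  crs <- obj$crs$properties$name
  if (is.null(crs)) stop("vector layer has no CRS: ", path)
  feats <- obj$features
  geoms <- lapply(feats, function(f) {
    g <- f$geometry
    if (g$type == "Point") {
      as.numeric(unlist(g$coordinates))
    } else if (g$type == "Polygon") {
      ring <- g$coordinates[[1]]
      do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    } else stop("unsupported geometry type: ", g$type)
  })
  props <- lapply(feats, function(f) {
    p <- f$properties
    lapply(p, function(v) if (is.null(v)) NA else v)
  })
  if (length(props) && length(props[[1]])) {
    tab <- tibble::as_tibble(do.call(
      rbind, lapply(props, function(p) as.data.frame(p, stringsAsFactors = FALSE))))
  } else {
    tab <- tibble::tibble(.rows = length(geoms))
  }
  tab$geometry <- geoms
  vector_layer(tab, crs = crs)
}

# ---- plain geometry helpers (projected coordinates, metres) ----------------

#' Polygon area (shoelace)
#' @param ring closed two-column ring matrix.
#' @return area in map units squared.
#' @export
poly_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Polygon centroid (area-weighted)
#' @param ring closed two-column ring matrix.
#' @return numeric (x, y).
#' @export
poly_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- length(x)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x[-n]), mean(y[-n])))
  c(sum((x[-n] + x[-1]) * cr), sum((y[-n] + y[-1]) * cr)) / (6 * a)
}

#' Point-in-polygon test (even-odd ray casting)
#' @param px,py point coordinates (vectorised).
#' @param ring closed two-column ring matrix.
#' @return logical vector; boundary points count as inside.
#' @export
point_in_poly <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  inside <- logical(length(px))
  j <- n - 1L
  for (i in seq_len(n - 1L)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  on_edge <- dist_point_poly(px, py, ring) < 1e-9
  inside | on_edge
}

#' Distance from points to a polygon boundary or point geometry
#'
#' Zero is returned for points on the boundary; use together with
#' [point_in_poly()] for signed logic.
#' @param px,py point coordinates (vectorised).
#' @param geom polygon ring matrix or length-2 point.
#' @return numeric distances.
#' @export
dist_point_poly <- function(px, py, geom) {
  if (!is.matrix(geom)) return(sqrt((px - geom[1])^2 + (py - geom[2])^2))
  n <- nrow(geom)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n - 1L)) {
    ax <- geom[i, 1]; ay <- geom[i, 2]
    bx <- geom[i + 1L, 1]; by <- geom[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Distance from points to a polygon, 0 inside
#' @inheritParams dist_point_poly
#' @return numeric distances, 0 for interior points.
#' @export
dist_to_geom <- function(px, py, geom) {
  d <- dist_point_poly(px, py, geom)
  if (is.matrix(geom)) d[point_in_poly(px, py, geom)] <- 0
  d
}

#' Regular polygon approximation of an ellipse
#' @param cx,cy centre; `a`,`b` semi-axes (m); `theta` rotation (radians).
#' @param n vertices.
#' @return closed ring matrix.
#' @export
ellipse_polygon <- function(cx, cy, a, b, theta = 0, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)
  x0 <- a * cos(t); y0 <- b * sin(t)
  cbind(x = cx + x0 * cos(theta) - y0 * sin(theta),
        y = cy + x0 * sin(theta) + y0 * cos(theta))
}

#' Rectangle ring from bounds
#' @param xmin,ymin,xmax,ymax bounds.
#' @return closed ring matrix.
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin, xmin),
        y = c(ymin, ymin, ymax, ymax, ymin))
}

#' Fraction of a polygon's area lying within `buffer_m` of any of a set of
#' geometries, by fine rasterisation
#'
#' @param poly target polygon ring.
#' @param geoms list of polygon rings / points.
#' @param buffer_m buffer distance applied to `geoms` (0 = plain coverage).
#' @param res rasterisation step in metres.
#' @return covered fraction in [0, 1].
#' @export
coverage_fraction <- function(poly, geoms, buffer_m = 0, res = 0.25) {
  bb <- c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
  xs <- seq(bb[1] + res / 2, bb[3], by = res)
  ys <- seq(bb[2] + res / 2, bb[4], by = res)
  g <- expand.grid(x = xs, y = ys)
  inside <- point_in_poly(g$x, g$y, poly)
  if (!any(inside)) return(0)
  gx <- g$x[inside]; gy <- g$y[inside]
  covered <- rep(FALSE, length(gx))
  for (geom in geoms) {
    todo <- !covered
    if (!any(todo)) break
    covered[todo] <- dist_to_geom(gx[todo], gy[todo], geom) <= buffer_m
  }
  mean(covered)
}
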