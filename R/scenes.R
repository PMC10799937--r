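#' Parameters for synthetic NAIP-like scenes
#'
#' The generator paints live-canopy background and dead-tree crowns as
#' overlapping ellipses in a 4-band (R, G, B, NIR) image at 0.6 m ground
#' sample distance, together with exhaustive truth (crown polygons and an
#' instance label raster). Brown-stage crowns use a warm brown palette
#' (chromatic, red-family hue), grey-stage crowns a cool ash palette
#' (near-achromatic with a slight blue tint); both palettes are constructed
#' so that their mean colours classify correctly under the HSV staging
#' scores, and dead crowns carry low NIR relative to live canopy.
#'
#' @param extent_m scene width/height in metres.
#' @param gsd ground sample distance, metres per pixel.
#' @param n_crowns number of dead-tree crowns.
#' @param radius_log_mean,radius_log_sd lognormal parameters of the crown
#'   semi-major axis in metres.
#' @param radius_min floor on the semi-major axis (draws below it are
#'   redrawn). Keeps every simulated crown above the instance-extraction
#'   speckle floor: the smallest crown (1.5 m by 0.7 axis ratio) covers
#'   about 11 pixels at 0.6 m GSD.
#' @param axis_ratio_range range of the minor/major axis ratio.
#' @param clustering fraction of crowns placed in touching clumps.
#' @param clump_size_mean mean clump size (truncated Poisson, >= 2).
#' @param clump_sep_range centre separation within clumps, as a multiple of
#'   the mean radius of the pair.
#' @param stage_mix fraction of crowns in brown stage (rest grey).
#' @param shear_range,scale_range scene-level affine (off-nadir) distortion.
#' @param noise_sd per-band additive Gaussian noise (DN).
#' @param crs projected CRS identifier.
#' @return a `scene_params` list.
#' @export
scene_params <- function(extent_m = 76.8, gsd = 0.6, n_crowns = 25L,
                         radius_log_mean = log(2.2), radius_log_sd = 0.25,
                         radius_min = 1.5,
                         axis_ratio_range = c(0.7, 1),
                         clustering = 0.4, clump_size_mean = 3,
                         clump_sep_range = c(1.2, 2.0),
                         stage_mix = 0.5,
                         shear_range = c(-0.15, 0.15),
                         scale_range = c(0.9, 1.1),
                         noise_sd = 4,
                         crs = "EPSG:32611") {
  stopifnot(clustering >= 0, clustering <= 1, stage_mix >= 0, stage_mix <= 1,
            exp(radius_log_mean) > gsd, noise_sd >= 0)
  p <- list(extent_m = extent_m, gsd = gsd, n_crowns = as.integer(n_crowns),
            radius_log_mean = radius_log_mean, radius_log_sd = radius_log_sd,
            radius_min = radius_min,
            axis_ratio_range = axis_ratio_range, clustering = clustering,
            clump_size_mean = clump_size_mean,
            clump_sep_range = clump_sep_range, stage_mix = stage_mix,
            shear_range = shear_range, scale_range = scale_range,
            noise_sd = noise_sd, crs = crs, palettes = default_palettes())
  class(p) <- "scene_params"
  p
}

# Palette boxes: per-band c(lo, hi) for the per-crown base colour.
# Brown: red-family hue (R > G > B) with high saturation; grey: slight
# blue tint (B > G > R) so hue-based scores vanish; live: green hue with
# high NIR; soil: dark (background class).
default_palettes <- function() {
  list(
    brown = rbind(R = c(130, 170), G = c(75, 108), B = c(45, 72),
                  N = c(50, 90)),
    grey  = rbind(R = c(168, 180), G = c(182, 194), B = c(196, 208),
                  N = c(60, 100)),
    live  = rbind(R = c(55, 75), G = c(95, 125), B = c(50, 70),
                  N = c(150, 220)),
    soil  = rbind(R = c(55, 75), G = c(45, 62), B = c(35, 52),
                  N = c(60, 100))
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

runifr <- function(n, range) stats::runif(n, range[1], range[2])

# Distorted ellipse from base (a, b, theta) and scene affine M: shape matrix
# A = M R diag(a, b); effective axes/orientation from its SVD.
distort_ellipse <- function(a, b, theta, M) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  A <- M %*% R %*% diag(c(a, b))
  s <- svd(A)
  a2 <- s$d[1]; b2 <- s$d[2]
  th2 <- atan2(s$u[2, 1], s$u[1, 1])
  list(a = a2, b = b2, theta = th2, A = A)
}

# Rasterise one ellipse: returns integer pixel indices (row, col) whose
# centres fall inside.
ellipse_pixels <- function(cx, cy, A, tile_nrow, tile_ncol, xmin, ymax, gsd) {
  Ai <- solve(A)
  rad <- max(svd(A)$d)
  c0 <- max(1L, floor((cx - rad - xmin) / gsd) + 1L)
  c1 <- min(tile_ncol, ceiling((cx + rad - xmin) / gsd))
  r0 <- max(1L, floor((ymax - (cy + rad)) / gsd) + 1L)
  r1 <- min(tile_nrow, ceiling((ymax - (cy - rad)) / gsd))
  if (c1 < c0 || r1 < r0) return(cbind(row = integer(), col = integer()))
  rows <- r0:r1; cols <- c0:c1
  xs <- xmin + (cols - 0.5) * gsd
  ys <- ymax - (rows - 0.5) * gsd
  px <- outer(rep(1, length(rows)), xs) - cx
  py <- outer(ys, rep(1, length(cols))) - cy
  u <- Ai[1, 1] * px + Ai[1, 2] * py
  v <- Ai[2, 1] * px + Ai[2, 2] * py
  ins <- which(u * u + v * v <= 1, arr.ind = TRUE)
  cbind(row = rows[ins[, 1]], col = cols[ins[, 2]])
}

#' Generate a synthetic scene with exhaustive ground truth
#'
#' Deterministic for a fixed `(params, seed)` pair. Crowns are placed either
#' isolated (pairwise disjoint, by rejection) or in touching clumps; the
#' scene-level affine distortion is applied consistently to the image and the
#' truth geometry. Overlapping crowns are painted in id order (later crown on
#' top) but every crown keeps its full polygon in the truth layer; the truth
#' instance raster records the visible (topmost) id per pixel.
#'
#' @param params a [scene_params()] list.
#' @param seed integer seed.
#' @param max_tries placement retries before giving up.
#' @return a `scene_bundle`: list with `image` (4-band uint8 `raster_tile`),
#'   `truth_crowns` (`vector_layer` with id, stage, centre, axes, clump id),
#'   `truth_instances` (integer label `raster_tile`), `params`, `seed`.
#' @export
generate_scene <- function(params, seed = 1L, max_tries = 200L) {
  with_seed(seed, {
    gsd <- params$gsd
    n_px <- as.integer(round(params$extent_m / gsd))
    extent <- n_px * gsd
    xmin <- 0; ymax <- extent
    n <- params$n_crowns
    pal <- params$palettes

    sh <- runifr(1, params$shear_range)
    sc <- runifr(2, params$scale_range)
    M <- matrix(c(sc[1], 0, sh, sc[2]), 2, 2)

    # ---- placement plan (re-drawn if overlap fully occludes a crown) ---
    crowns <- NULL; shapes <- NULL; img <- NULL; inst <- NULL
    for (attempt in seq_len(10L)) {
    if (n > 0) {
      n_clust <- round(params$clustering * n)
      clump_sizes <- integer(0)
      while (sum(clump_sizes) < n_clust) {
        s <- 2L + stats::rpois(1, max(params$clump_size_mean - 2, 0.01))
        clump_sizes <- c(clump_sizes, min(s, n_clust - sum(clump_sizes)))
      }
      clump_sizes <- clump_sizes[clump_sizes > 0]
      if (length(clump_sizes) && clump_sizes[length(clump_sizes)] == 1L &&
          length(clump_sizes) > 1L) {
        clump_sizes[1] <- clump_sizes[1] + 1L
        clump_sizes <- clump_sizes[-length(clump_sizes)]
      }
      n_iso <- n - sum(clump_sizes)

      a_all <- stats::rlnorm(n, params$radius_log_mean, params$radius_log_sd)
      for (t in seq_len(50)) {
        small <- a_all < params$radius_min
        if (!any(small)) break
        a_all[small] <- stats::rlnorm(sum(small), params$radius_log_mean,
                                      params$radius_log_sd)
      }
      a_all <- pmax(a_all, params$radius_min)
      q_all <- runifr(n, params$axis_ratio_range)
      th_all <- stats::runif(n, 0, pi)
      stage_all <- ifelse(stats::runif(n) < params$stage_mix, "brown", "grey")

      margin <- pmin(a_all + 1, extent / 3)
      cx <- numeric(n); cy <- numeric(n); clump_id <- integer(n)
      placed <- 0L
      ok_dist <- function(x, y, i, idx, min_mult) {
        if (!length(idx)) return(TRUE)
        d <- sqrt((x - cx[idx])^2 + (y - cy[idx])^2)
        all(d >= min_mult * (a_all[i] + a_all[idx]))
      }
      # isolated crowns: pairwise disjoint from everything placed so far
      for (i in seq_len(n_iso)) {
        done <- FALSE
        for (t in seq_len(max_tries)) {
          x <- stats::runif(1, margin[i], extent - margin[i])
          y <- stats::runif(1, margin[i], extent - margin[i])
          if (ok_dist(x, y, i, seq_len(placed), 1.15)) {
            cx[i] <- x; cy[i] <- y; clump_id[i] <- 0L
            placed <- placed + 1L; done <- TRUE; break
          }
        }
        if (!done) stop("crown packing failure: n_crowns too large for extent ",
                        extent, " m (isolated placement)")
      }
      # clumps: members touch (separation in clump_sep_range x mean radius)
      ci <- n_iso
      for (k in seq_along(clump_sizes)) {
        sz <- clump_sizes[k]
        ids <- (ci + 1L):(ci + sz)
        done <- FALSE
        for (t in seq_len(max_tries)) {
          mrg <- min(max(margin[ids]), extent / 3)
          x0 <- stats::runif(1, mrg, extent - mrg)
          y0 <- stats::runif(1, mrg, extent - mrg)
          # other clumps / isolated crowns must stay clear
          if (!ok_dist(x0, y0, ids[1],
                       seq_len(placed)[clump_id[seq_len(placed)] != k],
                       1.3)) next
          xs <- x0; ys <- y0
          okc <- TRUE
          for (j in seq_len(sz - 1L)) {
            sep <- runifr(1, params$clump_sep_range) *
              mean(a_all[ids[c(j, j + 1L)]])
            ang <- stats::runif(1, 0, 2 * pi)
            xs <- c(xs, xs[j] + sep * cos(ang))
            ys <- c(ys, ys[j] + sep * sin(ang))
          }
          if (all(xs > 1, xs < extent - 1, ys > 1, ys < extent - 1)) {
            cx[ids] <- xs; cy[ids] <- ys; clump_id[ids] <- k
            placed <- placed + sz; done <- TRUE; break
          }
          if (!okc) next
        }
        if (!done) stop("crown packing failure: could not place clump of ",
                        sz, " crowns in extent ", extent, " m")
        ci <- ci + sz
      }

      dist <- lapply(seq_len(n), function(i)
        distort_ellipse(a_all[i], q_all[i] * a_all[i], th_all[i], M))
      crowns <- tibble::tibble(
        id = seq_len(n), stage = stage_all,
        cx = cx, cy = cy,
        a = vapply(dist, `[[`, 0, "a"), b = vapply(dist, `[[`, 0, "b"),
        theta = vapply(dist, `[[`, 0, "theta"),
        clump_id = clump_id)
      shapes <- lapply(dist, `[[`, "A")
    }

    # ---- render --------------------------------------------------------
    base <- sapply(rownames(pal$live), function(bn)
      matrix(runifr(n_px * n_px, pal$live[bn, ]), n_px, n_px))
    img <- array(base, dim = c(n_px, n_px, 4))
    inst <- matrix(0L, n_px, n_px)
    occluded <- FALSE
    if (n > 0) {
      for (i in seq_len(n)) {
        pix <- ellipse_pixels(crowns$cx[i], crowns$cy[i], shapes[[i]],
                              n_px, n_px, xmin, ymax, gsd)
        if (nrow(pix) == 0) next
        box <- pal[[crowns$stage[i]]]
        colr <- vapply(rownames(box), function(bn) runifr(1, box[bn, ]), 0)
        idx <- cbind(pix, band = 1L)
        for (bnd in 1:4) {
          idx[, 3] <- bnd
          img[idx] <- colr[bnd]
        }
        inst[pix] <- i
      }
      vis <- tabulate(inst[inst > 0], nbins = n)
      occluded <- any(vis == 0)
      if (!occluded) crowns$n_px_visible <- vis
    }
    if (!occluded) break
    if (attempt == 10L)
      stop("crown packing failure: crown(s) fully occluded after overlap ",
           "rendering in 10 attempts; reduce n_crowns or clump overlap")
    }
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))

    truth <- if (n > 0) {
      geoms <- lapply(seq_len(n), function(i)
        ellipse_polygon(crowns$cx[i], crowns$cy[i], crowns$a[i], crowns$b[i],
                        crowns$theta[i]))
      vector_layer(dplyr::mutate(crowns, geometry = geoms), crs = params$crs)
    } else {
      vector_layer(tibble::tibble(
        id = integer(), stage = character(), cx = numeric(), cy = numeric(),
        a = numeric(), b = numeric(), theta = numeric(),
        clump_id = integer(), n_px_visible = integer(), geometry = list()),
        crs = params$crs)
    }

    structure(list(
      image = raster_tile(img, xmin, ymax, gsd, params$crs,
                          tags = list(kind = "synthetic_scene", seed = seed)),
      truth_crowns = truth,
      truth_instances = raster_tile(inst, xmin, ymax, gsd, params$crs,
                                    nodata = NULL,
                                    tags = list(kind = "instance_labels")),
      params = params, seed = seed), class = "scene_bundle")
  })
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("<scene_bundle> %d x %d px @ %g m, %d truth crowns, seed %d\n",
              rt_nrow(x$image), rt_ncol(x$image), x$image$px,
              nrow(x$truth_crowns), x$seed))
  invisible(x)
}

#' Simulate a field survey over a scene's truth crowns
#'
#' Emits one point per detected crown at a jittered centroid, emulating
#' opportunistic tree-level field observations.
#'
#' @param bundle a `scene_bundle`.
#' @param detectability per-crown detection probability in [0, 1].
#' @param jitter_sd isotropic Gaussian positional error, metres.
#' @param seed integer seed.
#' @param year survey year attribute.
#' @return a `vector_layer` of points (tree_id, year).
#' @export
generate_field_survey <- function(bundle, detectability = 0.8,
                                  jitter_sd = 2, seed = 1L, year = 2019L) {
  stopifnot(detectability >= 0, detectability <= 1)
  with_seed(seed, {
    tc <- bundle$truth_crowns
    keep <- which(stats::runif(nrow(tc)) < detectability)
    pts <- lapply(keep, function(i)
      c(tc$cx[i] + stats::rnorm(1, 0, jitter_sd),
        tc$cy[i] + stats::rnorm(1, 0, jitter_sd)))
    vector_layer(tibble::tibble(tree_id = tc$id[keep],
                                year = rep(as.integer(year), length(keep)),
                                geometry = pts),
                 crs = vl_crs(tc))
  })
}

#' Simulate damage-agent survey polygons and fire perimeters over a scene
#'
#' Produces overlapping rectangles with agent-code, survey-year and kind
#' attributes, constructed so that some crowns fall inside multi-layer
#' overlaps (resolution is the job of the attribution module).
#'
#' @param bundle a `scene_bundle`.
#' @param n_layers number of survey rectangles.
#' @param years survey years, ascending, recycled over layers.
#' @param include_fire add one fire perimeter rectangle.
#' @param fire_year year of the fire perimeter.
#' @param agent_pool level-4 codes sampled for survey layers (1-3 per layer).
#' @param seed integer seed.
#' @return a `vector_layer` of polygons (year, agents, kind).
#' @export
generate_agent_polygons <- function(bundle, n_layers = 3L,
                                    years = c(2016L, 2019L, 2020L),
                                    include_fire = TRUE, fire_year = 2020L,
                                    agent_pool = c("fir_engraver",
                                                   "mtn_pine_beetle",
                                                   "western_pine_beetle",
                                                   "defoliator_moth",
                                                   "root_disease", "drought"),
                                    seed = 1L) {
  stopifnot(!is.unsorted(years))
  with_seed(seed, {
    ext <- rt_extent(bundle$image)
    w <- ext["xmax"] - ext["xmin"]; h <- ext["ymax"] - ext["ymin"]
    mk_rect <- function() {
      x0 <- stats::runif(1, ext["xmin"] - 0.1 * w, ext["xmin"] + 0.5 * w)
      y0 <- stats::runif(1, ext["ymin"] - 0.1 * h, ext["ymin"] + 0.5 * h)
      rect_polygon(x0, y0, x0 + stats::runif(1, 0.4, 0.8) * w,
                   y0 + stats::runif(1, 0.4, 0.8) * h)
    }
    yr <- rep_len(as.integer(years), n_layers)
    rows <- lapply(seq_len(n_layers), function(i) {
      ags <- sort(sample(agent_pool, sample(1:3, 1)))
      list(year = yr[i], agents = list(ags), kind = "survey",
           geometry = list(mk_rect()))
    })
    tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    if (include_fire) {
      tab <- dplyr::bind_rows(tab, tibble::tibble(
        year = as.integer(fire_year), agents = list("fire"), kind = "fire",
        geometry = list(mk_rect())))
    }
    vector_layer(tab, crs = vl_crs(bundle$truth_crowns))
  })
}
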