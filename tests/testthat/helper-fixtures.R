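# Shared fixtures built in code.

# Label matrix with one filled disc.
disc_labels <- function(n = 32L, cx = 16, cy = 16, r = 10, id = 1L) {
  m <- matrix(0L, n, n)
  for (c in seq_len(n)) for (rw in seq_len(n))
    if ((rw - cy)^2 + (c - cx)^2 <= r^2) m[rw, c] <- id
  m
}

# Two horizontally touching discs.
touching_discs <- function(n = 48L, r = 10) {
  m <- disc_labels(n, cx = 14, cy = 24, r = r, id = 1L)
  m2 <- disc_labels(n, cx = 14 + 2 * r, cy = 24, r = r, id = 2L)
  m[m == 0L & m2 > 0L] <- 2L
  m
}

# Axis-aligned filled ellipse label matrix (semi-axes in pixels).
ellipse_labels <- function(n, cx, cy, a, b, id = 1L) {
  m <- matrix(0L, n, n)
  for (c in seq_len(n)) for (rw in seq_len(n))
    if (((c - cx) / a)^2 + ((rw - cy) / b)^2 <= 1) m[rw, c] <- id
  m
}

# Independent transcription of the HSV staging scores (scalar, direct):
# a second implementation kept deliberately separate from the package code.
oracle_stage_scores <- function(R, G, B, Cg = 5, Cr = 5, Cy = 1e7,
                                Cb = 1e4) {
  mx <- max(R, G, B) / 255
  mn <- min(R, G, B) / 255
  V <- mx
  S <- if (mx == 0) 0 else (mx - mn) / mx
  d <- mx - mn
  H <- if (d == 0) 0 else {
    r <- R / 255; g <- G / 255; b <- B / 255
    h <- if (mx == r) (g - b) / d else if (mx == g) 2 + (b - r) / d
    else 4 + (r - g) / d
    h <- h / 6
    if (h < 0) h + 1 else h
  }
  Hw <- if (H > 5 / 6) H - 1 else H
  Hg <- 1 - abs(H - 1 / 3) * 6
  Hr <- (1 / 2 - Hw) * 6 - 2
  f <- function(C, x) (C^x - 1) / (C - 1)
  Xg <- if (S == 0 || Hg < 0) 0 else f(Cg, min(Hg, 1))
  Xb <- if (S == 0 || Hr < 0) 0 else min(1, f(Cr, min(Hr, 1)))
  c(X_green = max(0, min(1, Xg)), X_brown = Xb,
    X_grey = if (V == 0) 0 else f(Cy, 1 - S),
    X_background = f(Cb, 1 - V))
}

# Small trained network shared across tests (built once per test run).
shared_trained_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- run_config(patch_size = 64L)
      patches <- make_patch_set(30, cfg, patch_px = 64L, seed = 31)
      ts <- train_network(patches, cfg, epochs = 6, lr = 2e-3,
                          batch_size = 6L, seed = 31)
      cache <<- list(ts = ts, cfg = cfg)
    }
    cache
  }
})

# Brute-force oracle: list covering polygons for one point and apply the
# year-precedence and fire rules directly, layer pair by layer pair.
oracle_agents <- function(x, y, layers) {
  tab <- tibble::as_tibble(layers)
  cov <- vapply(tab$geometry, function(g) point_in_poly(x, y, g), TRUE)
  surv <- tab[cov & tab$kind == "survey", ]
  fires <- tab[cov & tab$kind == "fire", ]
  agents <- character(0); yr <- -Inf
  if (nrow(surv)) {
    surv <- surv[order(surv$year), ]
    agents <- surv$agents[[1]]; yr <- surv$year[1]
    for (i in seq_len(nrow(surv))[-1]) {
      agents <- resolve_survey_overlap(agents, yr, surv$agents[[i]],
                                       surv$year[i])
      yr <- max(yr, surv$year[i])
    }
  }
  if (nrow(fires)) {
    for (i in seq_len(nrow(fires)))
      agents <- resolve_fire_overlap(agents, yr, fires$year[i])
  }
  sort(agents)
}

random_layers <- function(seed, n_surv = 3, n_fire = 1) {
  set.seed(seed)
  pool <- c("fir_engraver", "mtn_pine_beetle", "drought", "root_disease",
            "defoliator_moth")
  mk <- function(kind) {
    x0 <- runif(1, 0, 60); y0 <- runif(1, 0, 60)
    tibble::tibble(
      year = sample(2015:2021, 1),
      agents = list(if (kind == "fire") "fire"
                    else sort(sample(pool, sample(1:3, 1)))),
      kind = kind,
      geometry = list(rect_polygon(x0, y0, x0 + runif(1, 20, 60),
                                   y0 + runif(1, 20, 60))))
  }
  rows <- c(lapply(seq_len(n_surv), function(i) mk("survey")),
            lapply(seq_len(n_fire), function(i) mk("fire")))
  vector_layer(dplyr::bind_rows(rows))
}
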