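# Compact convolutional encoder-decoder with an ordinal energy head.
#
# Feature maps live as (B * Hp * Wp) x C matrices: one row per pixel, samples
# stacked, column-major within a sample, with a one-pixel zero border around
# every sample (Hp = H + 2). The border makes each 3x3 tap a contiguous row
# shift, so convolutions run as submatrix GEMMs in C++ (src/conv_ops.cpp);
# pooling and upsampling use precomputed interior index tables. The zero
# border is re-established after every nonlinearity.

# Padded row index of interior pixel (ri, ci), 1-based, for one sample.
pad_index <- function(ri, ci, Hp) ci * Hp + ri + 1L

# Index tables for one (H, W, B) geometry; H and W must be divisible by 4.
net_geometry <- function(H, W, B) {
  stopifnot(H %% 4L == 0L, W %% 4L == 0L)
  geom_level <- function(h, w) {
    hp <- h + 2L; np <- hp * (w + 2L)
    int1 <- rep((1:w) * hp, each = h) + rep(2:(h + 1L), times = w)
    bord1 <- setdiff(seq_len(np), int1)
    list(h = h, w = w, hp = hp, np = np,
         interior = as.vector(outer(int1, (seq_len(B) - 1L) * np, "+")),
         border = as.vector(outer(bord1, (seq_len(B) - 1L) * np, "+")),
         n_rows = np * B, n_int = h * w * B)
  }
  g1 <- geom_level(H, W)
  g2 <- geom_level(H %/% 2L, W %/% 2L)
  g3 <- geom_level(H %/% 4L, W %/% 4L)
  pool_tab <- function(fine, coarse) {
    h2 <- coarse$h; w2 <- coarse$w
    r2 <- rep(seq_len(h2), times = w2)
    c2 <- rep(seq_len(w2), each = h2)
    fidx <- function(dr, dc) pad_index(2L * r2 - 2L + dr, 2L * c2 - 2L + dc,
                                       fine$hp)
    f1 <- cbind(fidx(1L, 1L), fidx(2L, 1L), fidx(1L, 2L), fidx(2L, 2L))
    cidx1 <- pad_index(r2, c2, coarse$hp)
    f <- do.call(rbind, lapply(seq_len(B) - 1L, function(b) f1 + b * fine$np))
    ci <- as.vector(outer(cidx1, (seq_len(B) - 1L) * coarse$np, "+"))
    list(fine = f, coarse = ci)
  }
  up_tab <- function(coarse, fine) {
    rr <- rep(seq_len(fine$h), times = fine$w)
    cc <- rep(seq_len(fine$w), each = fine$h)
    src1 <- pad_index((rr + 1L) %/% 2L, (cc + 1L) %/% 2L, coarse$hp)
    dst1 <- pad_index(rr, cc, fine$hp)
    list(src = as.vector(outer(src1, (seq_len(B) - 1L) * coarse$np, "+")),
         dst = as.vector(outer(dst1, (seq_len(B) - 1L) * fine$np, "+")))
  }
  list(B = B, g1 = g1, g2 = g2, g3 = g3,
       p1 = pool_tab(g1, g2), p2 = pool_tab(g2, g3),
       u2 = up_tab(g3, g2), u1 = up_tab(g2, g1))
}

# Embed an (n_int x C) interior matrix into the padded layout.
pad_embed <- function(Xint, g) {
  X <- matrix(0, g$n_rows, ncol(Xint))
  X[g$interior, ] <- Xint
  X
}

maxpool_fw <- function(X, tab, g_out) {
  n <- nrow(tab$fine)
  Yi <- X[tab$fine[, 1], , drop = FALSE]
  sel <- matrix(tab$fine[, 1], n, ncol(X))
  for (k in 2:4) {
    Xk <- X[tab$fine[, k], , drop = FALSE]
    upd <- which(Xk > Yi)     # which() drops NAs from non-finite inputs
    Yi[upd] <- Xk[upd]
    sel[upd] <- matrix(tab$fine[, k], n, ncol(X))[upd]
  }
  Y <- matrix(0, g_out$n_rows, ncol(X))
  Y[tab$coarse, ] <- Yi
  list(Y = Y, sel = sel, n_in = nrow(X))
}

maxpool_bw <- function(dY, cache, tab) {
  dYi <- dY[tab$coarse, , drop = FALSE]
  dX <- matrix(0, cache$n_in, ncol(dY))
  for (c in seq_len(ncol(dY)))
    dX[cbind(cache$sel[, c], c)] <- dYi[, c]
  dX
}

upsample_fw <- function(X, tab, g_out) {
  Y <- matrix(0, g_out$n_rows, ncol(X))
  Y[tab$dst, ] <- X[tab$src, , drop = FALSE]
  Y
}

upsample_bw <- function(dY, tab, g_in) {
  acc <- rowsum(dY[tab$dst, , drop = FALSE], tab$src)
  dX <- matrix(0, g_in$n_rows, ncol(dY))
  dX[sort(unique(tab$src)), ] <- acc
  dX
}

bn_eps <- 1e-5

# Batch norm over interior pixels (border rows are zero by construction and
# excluded from the statistics via the n_int divisor).
bn_fw <- function(Z, p, run, n_int, train, momentum = 0.1) {
  if (train) {
    m <- colSums(Z) / n_int
    v <- colSums(Z * Z) / n_int - m * m
    run$mean <- (1 - momentum) * run$mean + momentum * m
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    m <- run$mean; v <- run$var
  }
  sd <- sqrt(pmax(v, 0) + bn_eps)
  xhat <- Z
  Y <- Z
  for (c in seq_along(m)) {       # column ops beat sweep() at these shapes
    xc <- (Z[, c] - m[c]) / sd[c]
    xhat[, c] <- xc
    Y[, c] <- xc * p$gamma[c] + p$beta[c]
  }
  list(Y = Y, run = run,
       cache = if (train) list(xhat = xhat, sd = sd, n_int = n_int)
       else NULL)
}

# dY must be zero on border rows; xhat there is ignored via those zeros.
bn_bw <- function(dY, cache, p) {
  N <- cache$n_int
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dZ <- dY
  for (c in seq_along(dgamma)) {
    dxc <- dY[, c] * p$gamma[c]
    dZ[, c] <- (dxc - dbeta[c] * p$gamma[c] / N -
                  xhat[, c] * (dgamma[c] * p$gamma[c] / N)) / cache$sd[c]
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

he_init <- function(fan_in, n_out, scale = 1) {
  matrix(stats::rnorm(fan_in * n_out, 0, scale * sqrt(2 / fan_in)),
         fan_in, n_out)
}

#' Build the ordinal-energy segmentation network
#'
#' A compact UNet-style encoder-decoder: two 3x3 conv + batch-norm + ReLU
#' blocks at full resolution, one block after each of two 2x2 max-pools,
#' then a mirrored decoder with nearest-neighbour upsampling and skip
#' concatenation, ending in a 1x1 head with one sigmoid unit per energy
#' level (the ordinal head; nesting is enforced afterwards by
#' [monotone_enforce()]). `width_preset = "small"` (base width 8, ~18k
#' parameters) is sized for CPU training; `"wide"` doubles every width.
#'
#' @param in_bands input bands (4: R, G, B, NIR).
#' @param K number of energy levels (sigmoid outputs).
#' @param width_preset `"small"` or `"wide"`.
#' @param seed seed for weight initialisation.
#' @return a `snag_net` object (weights, batch-norm state, architecture).
#' @export
build_network <- function(in_bands = 4L, K = 5L,
                          width_preset = c("small", "wide"), seed = 1L) {
  width_preset <- match.arg(width_preset)
  stopifnot(K >= 2)
  w <- if (width_preset == "small") 8L else 16L
  with_seed(seed, {
    mkconv <- function(cin, cout) list(W = he_init(9L * cin, cout),
                                       b = matrix(0, 1, cout))
    mkbn <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
    mkrun <- function(c) list(mean = rep(0, c), var = rep(1, c))
    params <- list(
      conv1 = mkconv(in_bands, w),        bn1 = mkbn(w),
      conv2 = mkconv(w, w),               bn2 = mkbn(w),
      conv3 = mkconv(w, 2L * w),          bn3 = mkbn(2L * w),
      conv4 = mkconv(2L * w, 4L * w),     bn4 = mkbn(4L * w),
      conv5 = mkconv(6L * w, 2L * w),     bn5 = mkbn(2L * w),
      conv6 = mkconv(3L * w, w),          bn6 = mkbn(w),
      head = list(W = he_init(w, K, scale = 0.5), b = matrix(0, 1, K)))
    running <- list(bn1 = mkrun(w), bn2 = mkrun(w), bn3 = mkrun(2L * w),
                    bn4 = mkrun(4L * w), bn5 = mkrun(2L * w), bn6 = mkrun(w))
    structure(list(params = params, running = running,
                   arch = list(in_bands = as.integer(in_bands),
                               K = as.integer(K), width = w,
                               preset = width_preset)),
              class = "snag_net")
  })
}

#' @export
print.snag_net <- function(x, ...) {
  n_par <- sum(vapply(unlist(x$params, recursive = FALSE), length, 0))
  cat(sprintf("<snag_net> preset %s (base width %d), K = %d, %d parameters\n",
              x$arch$preset, x$arch$width, x$arch$K, n_par))
  invisible(x)
}

block_fw <- function(X, g, conv, bnp, run, train) {
  Z <- conv3p_fw(X, conv$W, conv$b[1, ], g$hp, g$border)
  bn <- bn_fw(Z, bnp, run, g$n_int, train)
  A <- bn$Y
  A[A < 0] <- 0
  A[g$border, ] <- 0
  mask <- bn$Y > 0
  mask[g$border, ] <- FALSE
  list(A = A, run = bn$run,
       cache = if (train) list(X = X, g = g, bn = bn$cache, mask = mask)
       else NULL)
}

block_bw <- function(dA, cache, conv, bnp) {
  dY <- dA * cache$mask          # mask is FALSE on border rows
  g <- bn_bw(dY, cache$bn, bnp)
  dZ <- g$dZ
  dZ[cache$g$border, ] <- 0
  cg <- conv3p_bw(dZ, cache$X, conv$W, cache$g$hp)
  list(dX = cg$dX,
       grads = list(W = cg$dW, b = matrix(cg$db, 1), gamma = g$dgamma,
                    beta = g$dbeta))
}

# Forward pass. Xint: (B*H*W) x in_bands interior matrix of reflectances in
# [0, 1]; returns probs over interior pixels only.
net_forward <- function(net, Xint, geo, train = FALSE) {
  p <- net$params; r <- net$running
  X <- pad_embed(Xint, geo$g1)
  b1 <- block_fw(X, geo$g1, p$conv1, p$bn1, r$bn1, train)
  b2 <- block_fw(b1$A, geo$g1, p$conv2, p$bn2, r$bn2, train)
  pl1 <- maxpool_fw(b2$A, geo$p1, geo$g2)
  b3 <- block_fw(pl1$Y, geo$g2, p$conv3, p$bn3, r$bn3, train)
  pl2 <- maxpool_fw(b3$A, geo$p2, geo$g3)
  b4 <- block_fw(pl2$Y, geo$g3, p$conv4, p$bn4, r$bn4, train)
  up2 <- cbind(upsample_fw(b4$A, geo$u2, geo$g2), b3$A)
  b5 <- block_fw(up2, geo$g2, p$conv5, p$bn5, r$bn5, train)
  up1 <- cbind(upsample_fw(b5$A, geo$u1, geo$g1), b2$A)
  b6 <- block_fw(up1, geo$g1, p$conv6, p$bn6, r$bn6, train)
  feats <- b6$A[geo$g1$interior, , drop = FALSE]
  logits <- sweep(feats %*% p$head$W, 2, p$head$b[1, ], "+")
  probs <- 1 / (1 + exp(-logits))
  running <- list(bn1 = b1$run, bn2 = b2$run, bn3 = b3$run, bn4 = b4$run,
                  bn5 = b5$run, bn6 = b6$run)
  list(probs = probs, running = running,
       cache = if (train) list(b1 = b1$cache, b2 = b2$cache, b3 = b3$cache,
                               b4 = b4$cache, b5 = b5$cache, b6 = b6$cache,
                               pl1 = pl1, pl2 = pl2, head_in = feats,
                               probs = probs) else NULL)
}

# Backward pass from d(loss)/d(probs) (interior rows); returns gradients
# named like params.
net_backward <- function(net, geo, cache, dprobs) {
  p <- net$params
  w <- net$arch$width
  dlog <- dprobs * cache$probs * (1 - cache$probs)
  gh <- list(W = crossprod(cache$head_in, dlog),
             b = matrix(colSums(dlog), 1))
  dA6 <- matrix(0, geo$g1$n_rows, w)
  dA6[geo$g1$interior, ] <- dlog %*% t(p$head$W)
  g6 <- block_bw(dA6, cache$b6, p$conv6, p$bn6)
  dup1 <- g6$dX
  dA5 <- upsample_bw(dup1[, seq_len(2L * w), drop = FALSE], geo$u1, geo$g2)
  dB2a <- dup1[, (2L * w + 1L):(3L * w), drop = FALSE]
  g5 <- block_bw(dA5, cache$b5, p$conv5, p$bn5)
  dup2 <- g5$dX
  dA4 <- upsample_bw(dup2[, seq_len(4L * w), drop = FALSE], geo$u2, geo$g3)
  dB3a <- dup2[, (4L * w + 1L):(6L * w), drop = FALSE]
  g4 <- block_bw(dA4, cache$b4, p$conv4, p$bn4)
  dpl2 <- maxpool_bw(g4$dX, cache$pl2, geo$p2)
  g3 <- block_bw(dpl2 + dB3a, cache$b3, p$conv3, p$bn3)
  dpl1 <- maxpool_bw(g3$dX, cache$pl1, geo$p1)
  g2 <- block_bw(dpl1 + dB2a, cache$b2, p$conv2, p$bn2)
  g1 <- block_bw(g2$dX, cache$b1, p$conv1, p$bn1)
  list(conv1 = g1$grads[c("W", "b")], bn1 = g1$grads[c("gamma", "beta")],
       conv2 = g2$grads[c("W", "b")], bn2 = g2$grads[c("gamma", "beta")],
       conv3 = g3$grads[c("W", "b")], bn3 = g3$grads[c("gamma", "beta")],
       conv4 = g4$grads[c("W", "b")], bn4 = g4$grads[c("gamma", "beta")],
       conv5 = g5$grads[c("W", "b")], bn5 = g5$grads[c("gamma", "beta")],
       conv6 = g6$grads[c("W", "b")], bn6 = g6$grads[c("gamma", "beta")],
       head = gh)
}

#' Focal Tversky loss on ordinal level masks
#'
#' Per energy level j the soft Tversky index
#' `TI_j = (TP + s) / (TP + alpha*FP + beta*FN + s)` is computed over all
#' pixels (s = 1 is the smoothing constant, which also defines TI = 1 for an
#' empty level predicted empty); the loss is `mean_j (1 - TI_j)^gamma`.
#' With alpha = beta = 0.5 and gamma = 1 this is soft Dice loss. alpha >
#' beta weights false positives more, giving conservative dead-tree calls;
#' gamma > 1 focuses training on poorly fit levels.
#'
#' @param pred `(N x K)` matrix (or `H x W x K` array) of probabilities.
#' @param target matching matrix/array of 0/1 ordinal masks.
#' @param alpha,beta,gamma Tversky/focal parameters.
#' @param smooth smoothing constant.
#' @param grad also return d(loss)/d(pred).
#' @return scalar loss, or (with `grad`) list(loss, dpred).
#' @export
focal_tversky_loss <- function(pred, target, alpha = 0.4, beta = 0.6,
                               gamma = 2, smooth = 1, grad = FALSE) {
  if (length(dim(pred)) == 3L) {
    K <- dim(pred)[3]
    pred <- matrix(pred, ncol = K)
    target <- matrix(target, ncol = K)
  }
  stopifnot(all(dim(pred) == dim(target)))
  K <- ncol(pred)
  loss <- 0
  dpred <- if (grad) matrix(0, nrow(pred), K) else NULL
  for (j in seq_len(K)) {
    p <- pred[, j]; t <- target[, j]
    TP <- sum(p * t); FP <- sum(p * (1 - t)); FN <- sum((1 - p) * t)
    num <- TP + smooth
    den <- TP + alpha * FP + beta * FN + smooth
    TI <- num / den
    loss <- loss + (1 - TI)^gamma / K
    if (grad) {
      dTI <- -(gamma * (1 - TI)^(gamma - 1)) / K
      dnum <- t
      dden <- t + alpha * (1 - t) - beta * t
      dpred[, j] <- dTI * (dnum * den - num * dden) / (den * den)
    }
  }
  if (grad) list(loss = loss, dpred = dpred) else loss
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  flat <- unlist(params)
  list(m = flat * 0, v = flat * 0, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  g <- unlist(grads)
  flat <- unlist(params)
  stopifnot(length(g) == length(flat))
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  flat <- flat - lr * mh / (sqrt(vh) + eps)
  list(params = utils::relist(flat, params), state = state)
}
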