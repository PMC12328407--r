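# Internal tensor primitives with explicit forward caches and hand-derived
# backward passes. Feature maps are 4D arrays laid out (C, H, W, N) --
# channel-first so per-channel operations (depthwise kernels, batch-norm
# statistics, 1x1 convolutions) reduce to vectorised arithmetic and BLAS
# matrix products on matrix(x, C).

# ---- reflection padding ------------------------------------------------------

.pad_reflect <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  if (d[2L] <= p || d[3L] <= p) stopf("map too small for reflection pad %d", p)
  hidx <- c((p + 1L):2L, seq_len(d[2L]), (d[2L] - 1L):(d[2L] - p))
  widx <- c((p + 1L):2L, seq_len(d[3L]), (d[3L] - 1L):(d[3L] - p))
  x[, hidx, widx, , drop = FALSE]
}

# Adjoint of .pad_reflect: fold gradients at padded positions back onto their
# interior mirror sources.
.fold_reflect <- function(g, p, H, W) {
  if (p == 0L) return(g)
  gh <- g[, p + seq_len(H), , , drop = FALSE]
  for (j in seq_len(p)) {
    gh[, p + 2L - j, , ] <- gh[, p + 2L - j, , ] + g[, j, , ]
    gh[, H - j, , ] <- gh[, H - j, , ] + g[, p + H + j, , ]
  }
  gw <- gh[, , p + seq_len(W), , drop = FALSE]
  for (j in seq_len(p)) {
    gw[, , p + 2L - j, ] <- gw[, , p + 2L - j, ] + gh[, , j, ]
    gw[, , W - j, ] <- gw[, , W - j, ] + gh[, , p + W + j, ]
  }
  gw
}

# ---- dense 2D convolution (used for the stem and all 1x1 projections) -------

.conv2d_fwd <- function(x, W, b = NULL, stride = 1L) {
  d <- dim(x); k <- dim(W)[3L]; cout <- dim(W)[1L]
  p <- (k - 1L) %/% 2L
  xp <- .pad_reflect(x, p)
  dp <- dim(xp)
  out_h <- (dp[2L] - k) %/% stride + 1L
  out_w <- (dp[3L] - k) %/% stride + 1L
  acc <- matrix(0, cout, out_h * out_w * d[4L])
  for (i in seq_len(k)) for (j in seq_len(k)) {
    hs <- seq(i, by = stride, length.out = out_h)
    ws <- seq(j, by = stride, length.out = out_w)
    xs <- xp[, hs, ws, , drop = FALSE]
    acc <- acc + W[, , i, j] %*% matrix(xs, d[1L])
  }
  out <- array(acc, c(cout, out_h, out_w, d[4L]))
  if (!is.null(b)) out <- out + b
  list(out = out, cache = list(xp = xp, W = W, stride = stride, k = k, p = p,
                               in_dim = d, out_hw = c(out_h, out_w),
                               has_bias = !is.null(b)))
}

.conv2d_bwd <- function(dout, cache) {
  W <- cache$W; k <- cache$k; stride <- cache$stride
  cout <- dim(W)[1L]; cin <- dim(W)[2L]
  doutm <- matrix(dout, cout)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(cache$xp))
  oh <- cache$out_hw[1L]; ow <- cache$out_hw[2L]
  for (i in seq_len(k)) for (j in seq_len(k)) {
    hs <- seq(i, by = stride, length.out = oh)
    ws <- seq(j, by = stride, length.out = ow)
    xs <- cache$xp[, hs, ws, , drop = FALSE]
    dW[, , i, j] <- doutm %*% t(matrix(xs, cin))
    contrib <- array(t(W[, , i, j]) %*% doutm, c(cin, oh, ow, dim(dout)[4L]))
    dxp[, hs, ws, ] <- dxp[, hs, ws, , drop = FALSE] + contrib
  }
  dx <- .fold_reflect(dxp, cache$p, cache$in_dim[2L], cache$in_dim[3L])
  list(dx = dx, dW = dW,
       db = if (cache$has_bias) rowSums(doutm) else NULL)
}

# ---- depthwise (per-channel) convolution, stride 1 ---------------------------

.dwconv_fwd <- function(x, W) {
  d <- dim(x); k <- dim(W)[2L]; p <- (k - 1L) %/% 2L
  xp <- .pad_reflect(x, p)
  out <- array(0, d)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xs <- xp[, (i - 1L) + seq_len(d[2L]), (j - 1L) + seq_len(d[3L]), ,
             drop = FALSE]
    out <- out + xs * W[, i, j]
  }
  list(out = out, cache = list(xp = xp, W = W, k = k, p = p, in_dim = d))
}

.dwconv_bwd <- function(dout, cache) {
  d <- cache$in_dim; k <- cache$k; W <- cache$W
  dW <- array(0, dim(W))
  dxp <- array(0, dim(cache$xp))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    hs <- (i - 1L) + seq_len(d[2L]); ws <- (j - 1L) + seq_len(d[3L])
    xs <- cache$xp[, hs, ws, , drop = FALSE]
    dW[, i, j] <- rowSums(matrix(xs * dout, d[1L]))
    dxp[, hs, ws, ] <- dxp[, hs, ws, , drop = FALSE] + dout * W[, i, j]
  }
  list(dx = .fold_reflect(dxp, cache$p, d[2L], d[3L]), dW = dW)
}

# ---- batch normalisation -----------------------------------------------------

.bn_fwd <- function(x, gamma, beta, running_mean, running_var,
                    train = TRUE, eps = 1e-5, momentum = 0.1) {
  cdim <- dim(x)[1L]
  m <- matrix(x, cdim)
  if (train) {
    mu <- rowMeans(m)
    v <- rowMeans(m^2) - mu^2
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    n <- ncol(m)
    unbias <- if (n > 1L) n / (n - 1L) else 1
    running_var <- (1 - momentum) * running_var + momentum * v * unbias
  } else {
    mu <- running_mean; v <- running_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * inv
  out <- xhat * gamma + beta
  list(out = out,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, train = train,
                    n = length(x) / cdim, cdim = cdim),
       running_mean = running_mean, running_var = running_var)
}

.bn_bwd <- function(dout, cache) {
  cdim <- cache$cdim
  dgamma <- rowSums(matrix(dout * cache$xhat, cdim))
  dbeta <- rowSums(matrix(dout, cdim))
  dxhat <- dout * cache$gamma
  if (!cache$train) {
    return(list(dx = dxhat * cache$inv, dgamma = dgamma, dbeta = dbeta))
  }
  n <- cache$n
  s1 <- rowSums(matrix(dxhat, cdim))
  s2 <- rowSums(matrix(dxhat * cache$xhat, cdim))
  dx <- cache$inv * (dxhat - (s1 + cache$xhat * s2) / n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations -------------------------------------------------------------

.relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
.relu_bwd <- function(dout, mask) dout * mask

# ---- pooling -----------------------------------------------------------------

.maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  xp <- .pad_reflect(x, pad)
  dp <- dim(xp)
  oh <- (dp[2L] - k) %/% stride + 1L
  ow <- (dp[3L] - k) %/% stride + 1L
  best <- array(-Inf, c(d[1L], oh, ow, d[4L]))
  which_k <- array(0L, dim(best))
  idx <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    idx <- idx + 1L
    hs <- seq(i, by = stride, length.out = oh)
    ws <- seq(j, by = stride, length.out = ow)
    xs <- xp[, hs, ws, , drop = FALSE]
    upd <- xs > best
    best[upd] <- xs[upd]
    which_k[upd] <- idx
  }
  list(out = best, cache = list(which_k = which_k, k = k, stride = stride,
                                pad = pad, in_dim = d, pdim = dp,
                                out_hw = c(oh, ow)))
}

.maxpool_bwd <- function(dout, cache) {
  dxp <- array(0, cache$pdim)
  oh <- cache$out_hw[1L]; ow <- cache$out_hw[2L]
  idx <- 0L
  for (i in seq_len(cache$k)) for (j in seq_len(cache$k)) {
    idx <- idx + 1L
    hs <- seq(i, by = cache$stride, length.out = oh)
    ws <- seq(j, by = cache$stride, length.out = ow)
    dxp[, hs, ws, ] <- dxp[, hs, ws, , drop = FALSE] + dout * (cache$which_k == idx)
  }
  .fold_reflect(dxp, cache$pad, cache$in_dim[2L], cache$in_dim[3L])
}

.avgpool2_fwd <- function(x) {
  d0 <- dim(x)
  xp <- .pad_even(x)
  dp <- dim(xp)
  ih <- seq(1L, dp[2L], 2L); iw <- seq(1L, dp[3L], 2L)
  out <- (xp[, ih, iw, , drop = FALSE] + xp[, ih, iw + 1L, , drop = FALSE] +
          xp[, ih + 1L, iw, , drop = FALSE] +
          xp[, ih + 1L, iw + 1L, , drop = FALSE]) / 4
  list(out = out, cache = list(in_dim = d0, pdim = dp))
}

.avgpool2_bwd <- function(dout, cache) {
  dp <- cache$pdim
  dxp <- array(0, dp)
  ih <- seq(1L, dp[2L], 2L); iw <- seq(1L, dp[3L], 2L)
  q <- dout / 4
  dxp[, ih, iw, ] <- q
  dxp[, ih, iw + 1L, ] <- q
  dxp[, ih + 1L, iw, ] <- q
  dxp[, ih + 1L, iw + 1L, ] <- q
  H <- cache$in_dim[2L]; W <- cache$in_dim[3L]
  if (dp[2L] > H) {
    dxp[, H, , ] <- dxp[, H, , ] + dxp[, H + 1L, , ]
    dxp <- dxp[, seq_len(H), , , drop = FALSE]
  }
  if (dp[3L] > W) {
    dxp[, , W, ] <- dxp[, , W, ] + dxp[, , W + 1L, ]
    dxp <- dxp[, , seq_len(W), , drop = FALSE]
  }
  dxp
}

.gap_fwd <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L], d[2L] * d[3L], d[4L])
  out <- apply(xm, 3L, rowMeans)
  if (is.null(dim(out))) out <- matrix(out, d[1L], d[4L])
  list(out = out, cache = d)   # out: C x N
}

.gap_bwd <- function(dout, d) {
  dx <- array(0, d)
  sc <- 1 / (d[2L] * d[3L])
  for (n in seq_len(d[4L])) dx[, , , n] <- dout[, n] * sc
  dx
}
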