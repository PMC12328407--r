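# Orthonormal 2D Haar wavelet transform and its exact inverse.
#
# Internally everything operates on 4D arrays laid out (channels, H, W, batch)
# so the same code serves a single plane (C = N = 1) and a whole feature-map
# batch. The transform is orthonormal: filter rows have unit norm, so signal
# energy is conserved exactly and the adjoint equals the inverse -- which is
# what makes backpropagation through the wavelet cascade a pair of transform
# calls rather than bespoke calculus.

.as4d <- function(x) {
  if (length(dim(x) %||% integer(0)) == 4L) return(x)
  if (is.matrix(x)) return(array(x, c(1L, nrow(x), ncol(x), 1L)))
  stopf("expected a matrix or a 4D (C,H,W,N) array")
}

# Replicate-pad the trailing row/column so H and W are even.
.pad_even <- function(x) {
  d <- dim(x)
  if (d[2L] %% 2L == 1L) x <- x[, c(seq_len(d[2L]), d[2L]), , , drop = FALSE]
  if (d[3L] %% 2L == 1L) x <- x[, , c(seq_len(d[3L]), d[3L]), , drop = FALSE]
  x
}

# Single-level orthonormal Haar analysis of a (C,H,W,N) array.
# Odd spatial dims are replicate-padded first; the original dims are kept so
# synthesis can crop back.
.dwt4 <- function(x) {
  d0 <- dim(x)
  x <- .pad_even(x)
  d <- dim(x)
  ih <- seq(1L, d[2L], 2L); iw <- seq(1L, d[3L], 2L)
  a <- x[, ih, iw, , drop = FALSE]       # top-left of each 2x2 cell
  b <- x[, ih, iw + 1L, , drop = FALSE]  # top-right
  cc <- x[, ih + 1L, iw, , drop = FALSE] # bottom-left
  dd <- x[, ih + 1L, iw + 1L, , drop = FALSE]
  list(
    LL = (a + b + cc + dd) / 2,
    LH = (a - b + cc - dd) / 2,   # horizontal (column) detail
    HL = (a + b - cc - dd) / 2,   # vertical (row) detail
    HH = (a - b - cc + dd) / 2,
    H = d0[2L], W = d0[3L]
  )
}

# Synthesis: exact inverse of .dwt4, cropping back to (H, W).
.idwt4 <- function(sub, H = sub$H, W = sub$W) {
  u <- sub$LL; v <- sub$LH; w <- sub$HL; z <- sub$HH
  ds <- dim(u)
  out <- array(0, c(ds[1L], 2L * ds[2L], 2L * ds[3L], ds[4L]))
  ih <- seq(1L, 2L * ds[2L], 2L); iw <- seq(1L, 2L * ds[3L], 2L)
  out[, ih, iw, ] <- (u + v + w + z) / 2
  out[, ih, iw + 1L, ] <- (u - v + w - z) / 2
  out[, ih + 1L, iw, ] <- (u + v - w - z) / 2
  out[, ih + 1L, iw + 1L, ] <- (u - v - w + z) / 2
  out[, seq_len(H), seq_len(W), , drop = FALSE]
}

# Adjoint of (replicate-pad -> analysis): synthesise the gradient subbands at
# padded size, then fold the padded row/column back onto the true edge.
.dwt4_adj <- function(gsub, H, W) {
  g <- .idwt4(gsub, H = 2L * dim(gsub$LL)[2L], W = 2L * dim(gsub$LL)[3L])
  if (dim(g)[2L] > H) {
    g[, H, , ] <- g[, H, , ] + g[, H + 1L, , ]
    g <- g[, seq_len(H), , , drop = FALSE]
  }
  if (dim(g)[3L] > W) {
    g[, , W, ] <- g[, , W, ] + g[, , W + 1L, ]
    g <- g[, , seq_len(W), , drop = FALSE]
  }
  g
}

# Adjoint of (synthesis -> crop): zero-extend the gradient plane to the padded
# size, then analyse (no further padding can occur: dims are even).
.idwt4_adj <- function(grec, sub_h, sub_w) {
  d <- dim(grec)
  if (d[2L] < 2L * sub_h || d[3L] < 2L * sub_w) {
    full <- array(0, c(d[1L], 2L * sub_h, 2L * sub_w, d[4L]))
    full[, seq_len(d[2L]), seq_len(d[3L]), ] <- grec
    grec <- full
  }
  .dwt4(grec)
}

.check_haar <- function(wavelet) {
  if (!wavelet %in% c("haar", "db1"))
    stopf("unsupported wavelet family '%s' (orthonormal Haar only)", wavelet)
}

#' Single-level 2D discrete wavelet transform (orthonormal Haar)
#'
#' Decomposes a real matrix into four half-resolution subbands: the
#' low-frequency approximation `LL` and the horizontal / vertical / diagonal
#' detail bands `LH`, `HL`, `HH`. The transform is orthonormal, so
#' `sum(x^2) == sum(LL^2) + sum(LH^2) + sum(HL^2) + sum(HH^2)` and
#' [idwt2()] reconstructs the input exactly (to float tolerance). Matrices
#' with an odd number of rows or columns are replicate-padded by one line
#' before analysis; the original dimensions are stored so the inverse crops
#' back.
#'
#' @param x numeric matrix (H x W), non-empty.
#' @param wavelet wavelet family; only the orthonormal Haar family
#'   (`"haar"`, alias `"db1"`) is implemented.
#' @return list with matrix components `LL`, `LH`, `HL`, `HH` and the original
#'   dimensions `H`, `W`.
#' @examples
#' s <- dwt2(matrix(1:16, 4, 4))
#' max(abs(idwt2(s) - matrix(1:16, 4, 4)))
#' @export
dwt2 <- function(x, wavelet = "haar") {
  .check_haar(wavelet)
  if (!is.matrix(x) || length(x) == 0L) stopf("dwt2 needs a non-empty matrix")
  s <- .dwt4(.as4d(x))
  lapply2 <- function(f) matrix(f, dim(f)[2L], dim(f)[3L])
  list(LL = lapply2(s$LL), LH = lapply2(s$LH), HL = lapply2(s$HL),
       HH = lapply2(s$HH), H = s$H, W = s$W)
}

#' Inverse single-level 2D Haar transform
#'
#' Exact inverse of [dwt2()] within floating-point tolerance.
#'
#' @param subbands list as returned by [dwt2()] (`LL`, `LH`, `HL`, `HH`, and
#'   optionally `H`, `W` to crop a padded odd-sized input).
#' @return numeric matrix of size `H x W`.
#' @export
idwt2 <- function(subbands) {
  need <- c("LL", "LH", "HL", "HH")
  if (!all(need %in% names(subbands))) stopf("idwt2 needs LL, LH, HL, HH")
  dims <- vapply(subbands[need], function(m) dim(as.matrix(m)), integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stopf("subband shapes are inconsistent")
  sub <- lapply(subbands[need], function(m) .as4d(as.matrix(m)))
  H <- subbands$H %||% (2L * dims[1L, 1L])
  W <- subbands$W %||% (2L * dims[2L, 1L])
  out <- .idwt4(c(sub, list(H = H, W = W)))
  matrix(out, dim(out)[2L], dim(out)[3L])
}
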