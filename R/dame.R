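# DAME: dynamic adjacency matrix extraction.
#
# The label-dependency graph is seeded from annotation statistics -- a label
# co-occurrence count matrix M, its row-conditional probability matrix M',
# a confidence threshold tau producing a binary adjacency A, and a reweighting
# that balances self-loops (1 - p) against retained neighbours (total mass p)
# to fight over-smoothing. A multi-head scaled-dot-product graph transformer
# then refines the seeded graph N into the adjacency P consumed by the GCN.
# The attention block carries a residual connection and a zero-initialised
# output projection, so at initialisation P is exactly the (normalised)
# statistics graph and training moves it away from there.

#' Count label co-occurrences
#'
#' @param annotations binary `n_samples x C` matrix (1 = label present),
#'   optionally with label names as column names.
#' @return symmetric `C x C` co-occurrence count matrix; entry `(i, j)` is the
#'   number of samples carrying both labels, the diagonal holds per-label
#'   totals.
#' @examples
#' count_cooccurrence(rbind(c(1, 1), c(1, 0), c(0, 1)))
#' @export
count_cooccurrence <- function(annotations) {
  assert_binary_matrix(annotations, "annotation matrix")
  M <- crossprod(annotations)           # t(A) %*% A: pairwise sample counts
  storage.mode(M) <- "double"
  M
}

#' Conditional label probabilities
#'
#' Row-conditions the co-occurrence counts: entry `(i, j)` estimates
#' `P(label j | label i) = M[i, j] / M[i, i]`. Labels that never occur get a
#' zero off-diagonal row and a unit diagonal, leaving them as isolated
#' self-loop nodes instead of dividing by zero.
#'
#' @param M co-occurrence matrix from [count_cooccurrence()].
#' @return `C x C` matrix of conditional probabilities in `[0, 1]`.
#' @export
conditional_probabilities <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stopf("M must be square")
  occ <- diag(M)
  Mp <- M
  pos <- occ > 0
  Mp[pos, ] <- Mp[pos, , drop = FALSE] / occ[pos]
  Mp[!pos, ] <- 0
  diag(Mp)[!pos] <- 1
  Mp
}

#' Threshold the conditional-probability graph
#'
#' Keeps an edge wherever the conditional probability reaches `tau`
#' (boundary values map to 1), eliminating low-confidence edges.
#'
#' @param Mprime conditional probability matrix.
#' @param tau confidence threshold in `[0, 1]`; the reference configuration
#'   uses 0.4.
#' @return binary `C x C` adjacency matrix.
#' @export
binarize <- function(Mprime, tau = 0.4) {
  assert_prob(tau, "tau")
  (Mprime >= tau) * 1
}

#' Reweight the binary adjacency into the correlation graph
#'
#' Produces the graph `N` with self-loop weight `1 - p` on the diagonal and,
#' for each node with at least one retained neighbour, total off-diagonal
#' mass `p` split evenly over its neighbours:
#' `N[i, j] = p * A[i, j] / sum_{j != i} A[i, j]`. Isolated nodes keep a zero
#' off-diagonal row. `p = 0` returns the identity.
#'
#' @param A binary adjacency from [binarize()] (diagonal ignored: self-loops
#'   are represented by `1 - p`).
#' @param p neighbour mass in `[0, 1]`; the reference configuration uses 0.2.
#' @return `C x C` correlation graph matrix.
#' @export
reweight <- function(A, p = 0.2) {
  assert_prob(p, "p")
  if (!is.matrix(A) || nrow(A) != ncol(A)) stopf("A must be square")
  Aoff <- A
  diag(Aoff) <- 0
  deg <- rowSums(Aoff)
  N <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  nz <- deg > 0
  N[nz, ] <- p * Aoff[nz, , drop = FALSE] / deg[nz]
  diag(N) <- 1 - p
  N
}

#' Build the statistics-seeded correlation graph in one call
#'
#' Convenience wrapper: counts -> conditional probabilities -> threshold ->
#' reweighting.
#'
#' @param annotations binary annotation matrix.
#' @param tau,p see [binarize()] and [reweight()].
#' @return list with components `M`, `Mprime`, `A`, `N`.
#' @export
correlation_graph <- function(annotations, tau = 0.4, p = 0.2) {
  M <- count_cooccurrence(annotations)
  Mp <- conditional_probabilities(M)
  A <- binarize(Mp, tau)
  list(M = M, Mprime = Mp, A = A, N = reweight(A, p))
}

# ---- graph transformer -------------------------------------------------------

#' Initialise one attention head
#'
#' @param C number of label nodes.
#' @param d_h attention dimension (default 64).
#' @return list with Xavier-initialised `Wq`, `Wk`, `Wv` of shape `C x d_h`
#'   (draws from the current RNG stream).
#' @export
attention_head_params <- function(C, d_h = 64L) {
  list(Wq = xavier(C, d_h), Wk = xavier(C, d_h), Wv = xavier(C, d_h))
}

.attention_fwd <- function(N, params) {
  Q <- N %*% params$Wq
  K <- N %*% params$Wk
  V <- N %*% params$Wv
  d_h <- ncol(Q)
  S <- Q %*% t(K) / sqrt(d_h)
  S <- S - apply(S, 1L, max)            # numerically stable row softmax
  E <- exp(S)
  A <- E / rowSums(E)
  list(out = A %*% V, A = A, Q = Q, K = K, V = V, d_h = d_h)
}

.attention_bwd <- function(dout, N, params, cache) {
  A <- cache$A; V <- cache$V
  dV <- t(A) %*% dout
  dA <- dout %*% t(V)
  dS <- A * (dA - rowSums(dA * A))      # softmax Jacobian, row-wise
  dS <- dS / sqrt(cache$d_h)
  dQ <- dS %*% cache$K
  dK <- t(dS) %*% cache$Q
  list(dWq = t(N) %*% dQ, dWk = t(N) %*% dK, dWv = t(N) %*% dV,
       dN = dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv))
}

#' One scaled-dot-product attention head over the label graph
#'
#' Projects the correlation graph `N` to queries, keys and values, forms the
#' row-softmax attention matrix `softmax(Q K' / sqrt(d_h))` (rows sum to 1),
#' and applies it to `V`.
#'
#' @param N `C x C` correlation graph.
#' @param params head parameters (`Wq`, `Wk`, `Wv`, each `C x d_h`).
#' @return `C x d_h` matrix with the intermediate row-stochastic attention
#'   matrix in attribute `"attention"`.
#' @export
attention_head <- function(N, params) {
  if (!is.matrix(N) || nrow(N) != ncol(N)) stopf("N must be square")
  dims <- vapply(params[c("Wq", "Wk", "Wv")], dim, integer(2))
  if (any(dims[1L, ] != nrow(N)) || length(unique(dims[2L, ])) != 1L)
    stopf("head parameters must all be %d x d_h", nrow(N))
  f <- .attention_fwd(N, params)
  structure(f$out, attention = f$A)
}

#' Initialise one attention subgraph block
#'
#' @param C number of label nodes.
#' @param h heads per block (default 4).
#' @param d_h attention dimension per head (default 64).
#' @return list with `heads` (list of [attention_head_params()]) and the
#'   output projection `Wo` (`h * d_h x C`), zero-initialised so the block is
#'   the identity refinement at the start of training.
#' @export
subgraph_params <- function(C, h = 4L, d_h = 64L) {
  list(heads = lapply(seq_len(h), function(i) attention_head_params(C, d_h)),
       Wo = matrix(0, h * d_h, C))
}

.subgraph_fwd <- function(N, params) {
  hf <- lapply(params$heads, function(hp) .attention_fwd(N, hp))
  concat <- do.call(cbind, lapply(hf, `[[`, "out"))
  if (nrow(params$Wo) != ncol(concat) || ncol(params$Wo) != nrow(N))
    stopf("output projection must map %d -> %d", ncol(concat), nrow(N))
  pre <- N + concat %*% params$Wo      # residual around the attention block
  G <- pmax(pre, 0)
  list(out = G, heads = hf, concat = concat, pre = pre)
}

.subgraph_bwd <- function(dG, N, params, cache) {
  dpre <- dG * (cache$pre > 0)
  dWo <- t(cache$concat) %*% dpre
  dconcat <- dpre %*% t(params$Wo)
  d_h <- ncol(cache$heads[[1L]]$Q)
  dheads <- vector("list", length(params$heads))
  for (i in seq_along(params$heads)) {
    cols <- (i - 1L) * d_h + seq_len(d_h)
    dheads[[i]] <- .attention_bwd(dconcat[, cols, drop = FALSE], N,
                                  params$heads[[i]], cache$heads[[i]])
  }
  list(dWo = dWo, dheads = dheads)
}

#' Build one refined subgraph
#'
#' Concatenates the outputs of all heads, projects back to `C x C` with `Wo`,
#' adds the correlation graph as a residual, and rectifies negatives to zero.
#' With all parameters zero the subgraph equals `N` itself (the residual
#' seed).
#'
#' @param N `C x C` correlation graph.
#' @param heads list of head parameter lists.
#' @param Wo output projection, `h * d_h x C`.
#' @return nonnegative `C x C` subgraph matrix.
#' @export
build_subgraph <- function(N, heads, Wo) {
  .subgraph_fwd(N, list(heads = heads, Wo = Wo))$out
}

#' Compose subgraphs into the adjacency matrix
#'
#' Left-to-right matrix product of the subgraphs, rectified to nonnegative
#' entries and (by default) row-normalised to unit row sums before being
#' handed to the GCN; zero rows are left untouched.
#'
#' @param subgraphs non-empty list of nonnegative `C x C` matrices.
#' @param normalize logical; set `FALSE` to obtain the raw rectified product.
#' @return `C x C` adjacency matrix.
#' @export
compose_adjacency <- function(subgraphs, normalize = TRUE) {
  if (!is.list(subgraphs) || length(subgraphs) == 0L)
    stopf("need at least one subgraph")
  P <- Reduce(`%*%`, subgraphs)
  P <- pmax(P, 0)
  if (normalize) P <- row_normalize(P)
  P
}

#' Initialise the full graph-transformer parameter set
#'
#' @param C number of label nodes.
#' @param k number of subgraph blocks composed by matrix product (default 2).
#' @param h heads per block (default 4).
#' @param d_h attention dimension (default 64).
#' @param seed integer seed for the Xavier draws.
#' @return list of `k` [subgraph_params()] blocks.
#' @export
dame_params <- function(C, k = 2L, h = 4L, d_h = 64L, seed = 1L) {
  with_seed(seed, lapply(seq_len(k), function(j) subgraph_params(C, h, d_h)))
}

.dame_fwd <- function(N, params) {
  sg <- lapply(params, function(pj) .subgraph_fwd(N, pj))
  Gs <- lapply(sg, `[[`, "out")
  k <- length(Gs)
  prefix <- vector("list", k)          # prefix[[j]] = G_1 %*% ... %*% G_j
  prefix[[1L]] <- Gs[[1L]]
  if (k > 1L) for (j in 2L:k) prefix[[j]] <- prefix[[j - 1L]] %*% Gs[[j]]
  raw <- prefix[[k]]
  rect <- pmax(raw, 0)
  s <- rowSums(rect)
  P <- rect
  nz <- s > 0
  P[nz, ] <- P[nz, , drop = FALSE] / s[nz]
  list(P = P, cache = list(sg = sg, Gs = Gs, prefix = prefix, raw = raw,
                           rect = rect, s = s, nz = nz))
}

.dame_bwd <- function(dP, N, params, cache) {
  # row normalisation backward
  s <- cache$s; nz <- cache$nz; rect <- cache$rect
  drect <- matrix(0, nrow(dP), ncol(dP))
  if (any(nz)) {
    dPn <- dP[nz, , drop = FALSE]
    rn <- rect[nz, , drop = FALSE] / s[nz]
    drect[nz, ] <- (dPn - rowSums(dPn * rn)) / s[nz]
  }
  draw <- drect * (cache$raw > 0)
  k <- length(cache$Gs)
  dG <- vector("list", k)
  grad <- draw
  for (j in rev(seq_len(k))) {
    left <- if (j == 1L) NULL else cache$prefix[[j - 1L]]
    dG[[j]] <- if (is.null(left)) grad else t(left) %*% grad
    if (j > 1L) grad <- grad %*% t(cache$Gs[[j]])
  }
  lapply(seq_len(k), function(j)
    .subgraph_bwd(dG[[j]], N, params[[j]], cache$sg[[j]]))
}

#' Run the full DAME refinement
#'
#' @param N `C x C` correlation graph from [correlation_graph()] /
#'   [reweight()].
#' @param params parameter set from [dame_params()].
#' @return refined row-normalised adjacency matrix `P`.
#' @export
dame_forward <- function(N, params) {
  P <- .dame_fwd(N, params)$P
  dimnames(P) <- dimnames(N)
  P
}

#' Attention-stage operation count
#'
#' Number of attention weights computed for `C` label classes at attention
#' dimension `d`: `C^2 * d`. For 20 classes at `d = 64` this is 25,600; for
#' 60 classes it is 230,400.
#'
#' @param C number of label classes (>= 1).
#' @param d attention dimension (>= 1).
#' @return integer-valued count `C * C * d`.
#' @export
complexity_estimate <- function(C, d) {
  if (!is.numeric(C) || !is.numeric(d) || C < 1 || d < 1)
    stopf("C and d must be positive")
  as.numeric(C) * as.numeric(C) * as.numeric(d)
}
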