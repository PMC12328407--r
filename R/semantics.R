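# Label semantics: word-vector node features and the two-layer GCN that turns
# them into one linear classifier per label.

.stopwords <- c(
  "a", "an", "and", "are", "as", "at", "be", "by", "due", "for", "from",
  "in", "into", "is", "it", "of", "on", "or", "the", "to", "with")

#' Preprocess label names into token lists
#'
#' Lowercases, tokenizes on non-alphanumeric characters (hyphens split),
#' removes common English stop words, and Porter-stems every token. If
#' stop-word removal or stemming would leave a label with no tokens, the raw
#' lowercased tokens are kept instead.
#'
#' @param labels character vector of label names (non-empty strings).
#' @return object of class `label_vocabulary`: list with `labels` (the input
#'   order) and `tokens` (per-label character vectors of stems).
#' @examples
#' preprocess_labels(c("diabetic retinopathy", "normal"))
#' @export
preprocess_labels <- function(labels) {
  if (length(labels) == 0L) stopf("no labels given")
  if (any(!nzchar(trimws(labels)))) stopf("empty label string")
  if (anyDuplicated(labels)) stopf("duplicate label names")
  tokens <- lapply(labels, function(lab) {
    raw <- strsplit(tolower(lab), "[^a-z0-9]+")[[1L]]
    raw <- raw[nzchar(raw)]
    if (length(raw) == 0L) stopf("label '%s' has no tokens", lab)
    kept <- raw[!raw %in% .stopwords]
    if (length(kept) == 0L) kept <- raw
    stems <- vapply(kept, porter_stem, character(1), USE.NAMES = FALSE)
    stems <- stems[nzchar(stems)]
    if (length(stems) == 0L) kept else stems
  })
  structure(list(labels = labels, tokens = tokens),
            class = "label_vocabulary")
}

#' Read a GloVe-format embedding table
#'
#' One line per token: the token followed by its vector components,
#' space-separated, no header.
#'
#' @param path path to the text file.
#' @param dim expected vector dimension (default 300).
#' @return named list mapping token to numeric vector.
#' @export
read_embeddings <- function(path, dim = 300L) {
  if (!file.exists(path)) stopf("embedding file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  tab <- lapply(parts, function(p) as.numeric(p[-1L]))
  names(tab) <- vapply(parts, `[[`, character(1), 1L)
  lens <- lengths(tab)
  if (length(unique(lens)) > 1L)
    stopf("inconsistent embedding dimensions: %s", paste(unique(lens), collapse = ", "))
  if (length(tab) && lens[1L] != dim)
    stopf("embedding dimension %d, expected %d", lens[1L], dim)
  tab
}

.oov_vector <- function(token, dim, seed) {
  with_seed((hash_string(token) + seed) %% 2147483647, {
    v <- stats::rnorm(dim)
    v / sqrt(sum(v^2))
  })
}

#' Embed labels as the mean of their token vectors
#'
#' Each label's node feature is the mean of its tokens' word vectors.
#' Out-of-vocabulary tokens receive a deterministic unit-norm vector derived
#' from the token string and `seed` (reported via a warning), so the
#' embedding matrix is reproducible bit-for-bit across runs.
#'
#' @param vocab a [preprocess_labels()] result.
#' @param table named token -> vector list, e.g. from [read_embeddings()].
#' @param dim embedding dimension (default 300).
#' @param seed seed for out-of-vocabulary vectors.
#' @return `C x dim` matrix `H0` with labels as row names.
#' @export
embed_labels <- function(vocab, table, dim = 300L, seed = 1L) {
  if (length(table)) {
    lens <- lengths(table)
    if (length(unique(lens)) > 1L) stopf("inconsistent embedding dimensions")
    dim <- lens[[1L]]
  }
  H0 <- matrix(0, length(vocab$labels), dim,
               dimnames = list(vocab$labels, NULL))
  oov <- character(0)
  for (i in seq_along(vocab$labels)) {
    vecs <- lapply(vocab$tokens[[i]], function(tok) {
      if (!is.null(table[[tok]])) return(table[[tok]])
      oov <<- c(oov, tok)
      .oov_vector(tok, dim, seed)
    })
    H0[i, ] <- Reduce(`+`, vecs) / length(vecs)
  }
  if (length(oov))
    warning(sprintf("out-of-vocabulary tokens given seeded vectors: %s",
                    paste(unique(oov), collapse = ", ")), call. = FALSE)
  H0
}

#' Cosine similarity between two word vectors
#'
#' @param vi,vj nonzero numeric vectors of equal length.
#' @return `vi . vj / (||vi|| ||vj||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(vi, vj) {
  if (length(vi) != length(vj)) stopf("vectors differ in length")
  ni <- sqrt(sum(vi^2)); nj <- sqrt(sum(vj^2))
  if (ni == 0 || nj == 0) stopf("cosine similarity undefined for zero vector")
  sum(vi * vj) / (ni * nj)
}

#' Pairwise cosine similarities of the label embeddings
#'
#' Exported for inspection of the semantic structure; the default pipeline
#' builds the label graph from co-occurrence statistics, not from these.
#'
#' @param H0 embedding matrix from [embed_labels()].
#' @return symmetric `C x C` similarity matrix.
#' @export
label_cosine_matrix <- function(H0) {
  n <- sqrt(rowSums(H0^2))
  if (any(n == 0)) stopf("zero embedding row")
  S <- (H0 / n) %*% t(H0 / n)
  dimnames(S) <- list(rownames(H0), rownames(H0))
  S
}

# ---- GCN ---------------------------------------------------------------------

# symmetric normalised propagation matrix of P with self-loops
.gcn_prop <- function(P) {
  if (any(P < 0)) stopf("adjacency must be nonnegative (rectification is the graph module's job)")
  At <- P + diag(nrow(P))
  dh <- 1 / sqrt(rowSums(At))          # D_ii >= 1 thanks to the self-loop
  At * outer(dh, dh)
}

.gcn_layer_fwd <- function(H, P, Wl, activate, slope = 0.2) {
  S <- .gcn_prop(P)
  Z <- S %*% H %*% Wl
  out <- if (activate) leaky_relu(Z, slope) else Z
  list(out = out, cache = list(S = S, H = H, Wl = Wl, Z = Z,
                               activate = activate, slope = slope, P = P))
}

.gcn_layer_bwd <- function(dout, cache) {
  dZ <- if (cache$activate) dout * leaky_relu_grad(cache$Z, cache$slope)
        else dout
  SH <- cache$S %*% cache$H
  dWl <- t(SH) %*% dZ
  HW <- cache$H %*% cache$Wl
  dS <- dZ %*% t(HW)
  dH <- t(cache$S) %*% dZ %*% t(cache$Wl)
  # S = At * outer(dh, dh), At = P + I, dh_i = (sum_j At_ij)^(-1/2)
  At <- cache$P + diag(nrow(cache$P))
  dh <- 1 / sqrt(rowSums(At))
  dAt_direct <- dS * outer(dh, dh)
  # At[a, b] enters only degree d_a, which scales row a (via dh_i) and column
  # a (via dh_j) of S -- both corrections are therefore indexed by the row a
  r <- rowSums(dS * At * dh^3 %o% dh) / 2     # through dh_i in row a
  cvec <- colSums(dS * At * dh %o% dh^3) / 2  # through dh_j in column a
  dAt <- dAt_direct - outer(r + cvec, rep(1, nrow(At)))
  list(dH = dH, dWl = dWl, dP = dAt)
}

#' One graph-convolution layer
#'
#' Computes `sigma(D^{-1/2} (P + I) D^{-1/2} H Wl)` where `D` is the degree
#' matrix of `P + I` (so isolated nodes still propagate through their
#' self-loop). The activation is leaky ReLU (slope 0.2) and is applied only
#' when `activate = TRUE`.
#'
#' @param H `C x in_dim` node features.
#' @param P nonnegative `C x C` adjacency (negative entries are an error:
#'   rectification belongs to the graph-refinement stage).
#' @param Wl `in_dim x out_dim` weights.
#' @param activate apply the nonlinearity?
#' @return `C x out_dim` node features.
#' @export
gcn_layer <- function(H, P, Wl, activate = TRUE) {
  if (nrow(H) != nrow(P)) stopf("H and P disagree on node count")
  if (ncol(H) != nrow(Wl)) stopf("H and Wl shapes do not chain")
  .gcn_layer_fwd(H, P, Wl, activate)$out
}

#' Initialise GCN weights
#'
#' @param in_dim input feature width (300 for GloVe embeddings).
#' @param hidden hidden width (default 1024).
#' @param D output width = image-feature dimension (default 2048).
#' @param seed integer seed.
#' @return list with `W0` (`in_dim x hidden`) and `W1` (`hidden x D`).
#' @export
gcn_params <- function(in_dim = 300L, hidden = 1024L, D = 2048L, seed = 1L) {
  with_seed(seed, list(W0 = xavier(in_dim, hidden), W1 = xavier(hidden, D)))
}

.gcn_fwd <- function(H0, P, params) {
  l1 <- .gcn_layer_fwd(H0, P, params$W0, activate = TRUE)
  l2 <- .gcn_layer_fwd(l1$out, P, params$W1, activate = FALSE)
  list(W = l2$out, cache = list(l1 = l1$cache, l2 = l2$cache))
}

.gcn_bwd <- function(dW, cache) {
  g2 <- .gcn_layer_bwd(dW, cache$l2)
  g1 <- .gcn_layer_bwd(g2$dH, cache$l1)
  list(dW0 = g1$dWl, dW1 = g2$dWl, dP = g1$dP + g2$dP)
}

#' Two-layer GCN producing the label classifier
#'
#' Layer 1 applies the leaky-ReLU nonlinearity; layer 2 is linear and emits
#' the classifier matrix `W` with one `D`-dimensional row per label, later
#' fused with the pooled image feature as `Wx`.
#'
#' @param H0 `C x in_dim` label embedding matrix.
#' @param P nonnegative `C x C` adjacency.
#' @param params weights from [gcn_params()].
#' @return `C x D` classifier matrix.
#' @export
gcn_forward <- function(H0, P, params) {
  W <- .gcn_fwd(H0, P, params)$W
  rownames(W) <- rownames(H0)
  W
}
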