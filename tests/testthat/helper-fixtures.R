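# Shared fixtures, all generated in code.

# naive reference 2D correlation with interior-reflection padding, used as an
# independent oracle for the vectorised convolution code
ref_conv2d <- function(x, k) {
  p <- (nrow(k) - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  hidx <- c((p + 1L):2L, seq_len(H), (H - 1L):(H - p))
  widx <- c((p + 1L):2L, seq_len(W), (W - 1L):(W - p))
  xp <- x[hidx, widx]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- sum(xp[i:(i + 2L * p), j:(j + 2L * p)] * k)
  out
}

# tiny annotation fixture with block structure over four labels
toy_annotations <- function(n = 12L, seed = 5L) {
  set.seed(seed)
  y <- matrix(rbinom(n * 4L, 1L, 0.5), n, 4L)
  colnames(y) <- c("alpha", "beta", "gamma", "delta")
  y[rowSums(y) == 0, 1L] <- 1
  y
}

# a fully assembled miniature model (32px input) for training-dynamics tests
tiny_model <- function(seed = 9L, n = 6L) {
  spec <- backbone_spec("test", input_size = 32L, stem_channels = 4L,
                        num_blocks = 2L, num_layers = 2L, growth = 3L,
                        final_channels = 6L, levels = 1L)
  ann <- toy_annotations(n = n, seed = seed)
  emb <- make_embeddings(colnames(ann), dim = 12L, seed = seed)
  cfg <- meddgtn_config("test", k = 2L, h = 2L, d_h = 5L, hidden = 7L,
                        backbone = spec, seed = seed)
  model <- meddgtn(ann, emb, cfg)
  set.seed(seed + 1L)
  images <- array(runif(3L * 32L * 32L * n), c(3L, 32L, 32L, n))
  list(model = model, cfg = cfg,
       dataset = list(images = images, y = ann))
}
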