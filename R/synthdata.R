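# Seeded synthetic multi-label image data.
#
# The generator emulates the structure the model is built to exploit: labels
# co-activate in planted blocks (so the co-occurrence graph has recoverable
# structure), and each active label contributes a characteristic broad
# (low-spatial-frequency) Gaussian lesion at a fixed grid position, on top of
# high-frequency pixel noise (so the low-frequency-oriented backbone has a
# real signal to pool). A fixture word-embedding table in GloVe text format
# makes the semantics branch runnable offline.

#' Synthetic dataset specification
#'
#' @param C number of label classes (default 8).
#' @param n number of samples.
#' @param blocks number of co-occurrence blocks (labels are split evenly), or
#'   an explicit list of label-index vectors partitioning `1:C`.
#' @param p_within,p_between per-label activation probabilities inside /
#'   outside the sample's block (defaults 0.6 / 0.05).
#' @param image_size square image side (default 112; 448 supported).
#' @param lesion_sigma_low Gaussian lesion width in pixels (default
#'   `image_size / 10`: a broad, low-frequency blob).
#' @param noise_sigma s.d. of the additive high-frequency pixel noise
#'   (default 0.05).
#' @param labels optional label names; defaults to synthetic lesion names.
#' @param seed integer seed; every generated artefact is a pure function of
#'   the spec.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(C = 8L, n = 100L, blocks = 2L,
                       p_within = 0.6, p_between = 0.05,
                       image_size = 112L, lesion_sigma_low = NULL,
                       noise_sigma = 0.05, labels = NULL, seed = 1L) {
  C <- as.integer(C); n <- as.integer(n); image_size <- as.integer(image_size)
  if (C < 1L || n < 1L) stopf("C and n must be positive")
  assert_prob(p_within, "p_within"); assert_prob(p_between, "p_between")
  if (is.numeric(blocks) && length(blocks) == 1L) {
    k <- as.integer(blocks)
    blocks <- split(seq_len(C), rep(seq_len(k), length.out = C) |> sort())
  }
  got <- sort(as.integer(unlist(blocks, use.names = FALSE)))
  if (!identical(got, seq_len(C))) stopf("blocks must partition 1:%d", C)
  if (is.null(labels)) {
    # distinctive one-word names, as real disease vocabularies have
    stock <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
               "theta", "iota", "kappa", "lambda", "omicron", "sigma",
               "upsilon", "omega", "rho")
    labels <- if (C <= length(stock)) stock[seq_len(C)]
              else sprintf("lesion%02d", seq_len(C))
  }
  if (length(labels) != C) stopf("need %d label names", C)
  if (is.null(lesion_sigma_low)) lesion_sigma_low <- image_size / 10
  structure(list(C = C, n = n, blocks = unname(blocks),
                 p_within = p_within, p_between = p_between,
                 image_size = image_size,
                 lesion_sigma_low = lesion_sigma_low,
                 noise_sigma = noise_sigma, labels = labels,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Sample a planted-block annotation matrix
#'
#' Per sample: pick a block uniformly, activate each in-block label with
#' `p_within` and each out-of-block label with `p_between`; all-zero rows are
#' resampled (bounded retries) so every image carries at least one label.
#'
#' @param spec a [synth_spec()].
#' @return binary `n x C` matrix with label names as column names;
#'   bitwise-reproducible from `spec$seed`.
#' @export
sample_labels <- function(spec) {
  if (spec$p_within == 0 && spec$p_between == 0)
    stopf("impossible spec: all activation probabilities are zero")
  with_seed(spec$seed, {
    k <- length(spec$blocks)
    y <- matrix(0, spec$n, spec$C, dimnames = list(NULL, spec$labels))
    for (i in seq_len(spec$n)) {
      for (try in seq_len(1000L)) {
        b <- sample.int(k, 1L)
        pr <- rep(spec$p_between, spec$C)
        pr[spec$blocks[[b]]] <- spec$p_within
        row <- as.numeric(stats::runif(spec$C) < pr)
        if (sum(row) > 0) break
      }
      if (sum(row) == 0) stopf("failed to draw a non-empty label set")
      y[i, ] <- row
    }
    y
  })
}

#' Lesion template for one label
#'
#' A broad Gaussian blob of width `lesion_sigma_low` centred on a fixed grid
#' position keyed by the label index, amplitude 0.6.
#'
#' @param j label index in `1:C`.
#' @param spec a [synth_spec()].
#' @return `image_size x image_size` matrix.
#' @export
label_template <- function(j, spec) {
  S <- spec$image_size
  g <- ceiling(sqrt(spec$C))
  r <- (j - 1L) %/% g; cl <- (j - 1L) %% g
  cy <- (r + 0.5) / g * S; cx <- (cl + 0.5) / g * S
  yy <- matrix(seq_len(S), S, S)
  xx <- t(yy)
  0.6 * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * spec$lesion_sigma_low^2))
}

#' Render one synthetic image
#'
#' Grey canvas (level 0.1) plus the lesion templates of all active labels
#' plus i.i.d. Gaussian pixel noise of s.d. `noise_sigma` (drawn from the
#' current RNG stream), clipped to `[0, 1]` and replicated to three channels.
#'
#' @param label_vector binary length-`C` vector with at least one active
#'   label.
#' @param spec a [synth_spec()].
#' @return array `(3, image_size, image_size)` in `[0, 1]`.
#' @export
render_image <- function(label_vector, spec) {
  if (length(label_vector) != spec$C) stopf("label vector length != C")
  if (sum(label_vector) == 0) stopf("every image needs at least one active label")
  S <- spec$image_size
  canvas <- matrix(0.1, S, S)
  for (j in which(label_vector == 1)) canvas <- canvas + label_template(j, spec)
  if (spec$noise_sigma > 0)
    canvas <- canvas + matrix(stats::rnorm(S * S, sd = spec$noise_sigma), S, S)
  canvas <- pmin(pmax(canvas, 0), 1)
  out <- array(0, c(3L, S, S))
  for (ch in 1:3) out[ch, , ] <- canvas
  out
}

#' Generate a full synthetic dataset
#'
#' Composes [sample_labels()] and [render_image()]; if `dir` is given, also
#' writes `images/img_%04d.png` and a pipe-dialect `labels.csv` in exactly
#' the formats the CLI reads back.
#'
#' @param spec a [synth_spec()].
#' @param dir optional output directory.
#' @return list with `images` (`(3, S, S, n)` array), `annotations`
#'   (binary `n x C` matrix with image ids as row names), `spec`, and `dir`.
#' @export
make_dataset <- function(spec, dir = NULL) {
  ann <- sample_labels(spec)
  S <- spec$image_size
  images <- array(0, c(3L, S, S, spec$n))
  for (i in seq_len(spec$n)) {
    images[, , , i] <- with_seed(spec$seed + 1000L + i,
                                 render_image(ann[i, ], spec))
  }
  ids <- sprintf("img_%04d", seq_len(spec$n))
  rownames(ann) <- ids
  if (!is.null(dir)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(spec$n)) {
      plane <- images[1L, , , i]        # grayscale-replicated: store once
      rgb <- array(0, c(S, S, 3L))
      for (ch in 1:3) rgb[, , ch] <- images[ch, , , i]
      png::writePNG(rgb, file.path(img_dir, paste0(ids[i], ".png")))
    }
    write_annotations(ann, file.path(dir, "labels.csv"), dialect = "pipe")
  }
  list(images = images, annotations = ann, spec = spec, dir = dir)
}

#' Write a fixture word-embedding table
#'
#' One deterministic unit vector per distinct token of the label set, in
#' GloVe text format. Tokens that occur in the labels of exactly one
#' co-occurrence block additionally receive that block's shared component
#' (weight `mix`) before renormalisation, so within-block token pairs have
#' markedly higher cosine similarity than between-block pairs.
#'
#' @param labels character label names.
#' @param dim embedding dimension (default 300).
#' @param seed integer seed.
#' @param path optional output file; when `NULL` only the table is returned.
#' @param blocks optional list of label-index vectors (as in [synth_spec()]).
#' @param mix weight of the shared block component (default 1).
#' @return (invisibly when writing) the named token -> vector list.
#' @export
make_embeddings <- function(labels, dim = 300L, seed = 1L, path = NULL,
                            blocks = NULL, mix = 1) {
  if (length(labels) == 0L) stopf("no labels")
  vocab <- preprocess_labels(labels)
  tokens <- unique(unlist(vocab$tokens))
  block_of_token <- rep(NA_integer_, length(tokens))
  names(block_of_token) <- tokens
  if (!is.null(blocks)) {
    for (tok in tokens) {
      in_labels <- which(vapply(vocab$tokens, function(t) tok %in% t,
                                logical(1)))
      bs <- unique(vapply(in_labels, function(li)
        which(vapply(blocks, function(b) li %in% b, logical(1)))[1L],
        integer(1)))
      if (length(bs) == 1L) block_of_token[tok] <- bs
    }
    block_dirs <- lapply(seq_along(blocks), function(b)
      with_seed(seed + 7000L + b, {
        v <- stats::rnorm(dim); v / sqrt(sum(v^2))
      }))
  }
  tab <- lapply(tokens, function(tok) {
    v <- .oov_vector(tok, dim, seed)
    b <- block_of_token[[tok]]
    if (!is.na(b)) v <- v + mix * block_dirs[[b]]
    v / sqrt(sum(v^2))
  })
  names(tab) <- tokens
  if (!is.null(path)) {
    write_embeddings(tab, path)
    return(invisible(tab))
  }
  tab
}
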