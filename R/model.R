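# Full model: statistics-seeded attention-refined label graph (DAME) + GCN
# label classifier over word-vector node features + wavelet-conv dense image
# backbone, fused by an inner product and trained end-to-end with SGD.

#' Training configuration
#'
#' Defaults follow the reference recipe: SGD with momentum 0.9 and weight
#' decay 1e-4, initial learning rate 0.5 for the graph branch (DAME +
#' GCN) and 0.03 for the CNN branch, 100 epochs with both rates decaying to
#' 1/10 of their current value every 30 epochs, batch size 16, and early
#' stopping (patience 10 epochs on the monitored mAP, best weights restored).
#'
#' @param lr_graph,lr_cnn initial learning rates of the two parameter groups.
#' @param momentum,weight_decay SGD momentum and L2 weight decay.
#' @param epochs,batch_size training length and batch size.
#' @param decay_every,decay_factor step-decay schedule (multiplicative).
#' @param patience early-stopping patience in epochs on the monitored mAP.
#' @param threshold decision threshold for the P/R/F1 metrics.
#' @param seed integer seed controlling shuffling and any stochastic step.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr_graph = 0.5, lr_cnn = 0.03, momentum = 0.9,
                         weight_decay = 1e-4, epochs = 100L, batch_size = 16L,
                         decay_every = 30L, decay_factor = 0.1,
                         patience = 10L, threshold = 0.5, seed = 1L) {
  if (epochs < 0L) stopf("epochs must be >= 0")
  if (batch_size < 1L || decay_every < 1L || patience < 1L)
    stopf("batch_size, decay_every and patience must be positive")
  if (lr_graph <= 0 || lr_cnn <= 0) stopf("learning rates must be positive")
  structure(list(lr_graph = lr_graph, lr_cnn = lr_cnn, momentum = momentum,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 decay_every = as.integer(decay_every),
                 decay_factor = decay_factor, patience = as.integer(patience),
                 threshold = threshold, seed = as.integer(seed)),
            class = "train_config")
}

#' Model configuration
#'
#' Collects every tunable of the pipeline. Graph defaults are the reference
#' values `tau = 0.4`, `p = 0.2`; the attention stage uses `k = 2` subgraph
#' blocks of `h = 4` heads at dimension `d_h = 64`; the GCN maps
#' 300 -> hidden -> D where D is the backbone's pooled feature width.
#'
#' @param profile `"default"` (448-input) or `"test"` (112-input reduced).
#' @param tau,p,k,h,d_h,hidden graph-branch tunables (see [binarize()],
#'   [reweight()], [dame_params()], [gcn_params()]).
#' @param graph_init `"stats"` builds the label graph purely from
#'   co-occurrence statistics; `"cosine"` averages in an edge graph built
#'   from label-embedding cosine similarities.
#' @param backbone a [backbone_spec()]; defaults to the profile's spec.
#' @param train a [train_config()]; when omitted, the `"default"` profile
#'   uses the reference recipe while the reduced `"test"` profile scales the
#'   learning rates down (`lr_graph = 0.05`, `lr_cnn = 0.01`) to match its
#'   much smaller feature dimensions and randomly initialised backbone.
#' @param seed master seed for parameter initialisation.
#' @return object of class `meddgtn_config`.
#' @export
meddgtn_config <- function(profile = c("default", "test"),
                           tau = 0.4, p = 0.2, k = 2L, h = 4L, d_h = 64L,
                           hidden = NULL, graph_init = c("stats", "cosine"),
                           backbone = NULL, train = NULL,
                           seed = 1L) {
  profile <- match.arg(profile)
  graph_init <- match.arg(graph_init)
  if (is.null(backbone)) backbone <- backbone_spec(profile)
  if (is.null(train))
    train <- if (profile == "default") train_config()
             else train_config(lr_graph = 0.05, lr_cnn = 0.01)
  if (is.null(hidden)) hidden <- if (profile == "default") 1024L else 64L
  assert_prob(tau, "tau"); assert_prob(p, "p")
  structure(list(profile = profile, tau = tau, p = p, k = as.integer(k),
                 h = as.integer(h), d_h = as.integer(d_h),
                 hidden = as.integer(hidden), graph_init = graph_init,
                 backbone = backbone, train = train, seed = as.integer(seed)),
            class = "meddgtn_config")
}

#' Fuse the label classifier with the image feature
#'
#' Per-label prediction scores as the inner products `yhat = W x`.
#'
#' @param W `C x D` classifier matrix from [gcn_forward()].
#' @param x length-`D` feature vector, or `D x N` matrix for a batch.
#' @return length-`C` score vector, or `N x C` score matrix for a batch.
#' @export
fuse <- function(W, x) {
  if (is.matrix(x)) {
    if (nrow(x) != ncol(W)) stopf("feature dim %d != classifier dim %d",
                                  nrow(x), ncol(W))
    return(t(W %*% x))
  }
  if (length(x) != ncol(W)) stopf("feature dim %d != classifier dim %d",
                                  length(x), ncol(W))
  as.numeric(W %*% x)
}

#' Multi-label binary cross-entropy loss
#'
#' Negative Bernoulli log-likelihood of the sigmoid-transformed logits,
#' summed over labels and mean-reduced over the batch. Computed in the
#' numerically stable softplus form.
#'
#' @param yhat logits: length-`C` vector or `n x C` matrix.
#' @param y binary truths of matching shape.
#' @return scalar loss (nonnegative).
#' @export
bce_loss <- function(yhat, y) {
  if (length(yhat) != length(y)) stopf("shape mismatch")
  if (any(y != 0 & y != 1)) stopf("y must be binary")
  # per-element: max(z, 0) - z y + log(1 + exp(-|z|))
  el <- pmax(yhat, 0) - yhat * y + log1p(exp(-abs(yhat)))
  n <- if (is.matrix(yhat)) nrow(yhat) else 1L
  sum(el) / n
}

# ---- model assembly ----------------------------------------------------------

#' Construct a Med-DGTN model
#'
#' Builds the statistics-seeded label graph from the training annotations,
#' embeds the label names, and initialises all parameters from `config$seed`.
#'
#' @param annotations binary `n x C` training annotation matrix with label
#'   names as column names.
#' @param embeddings token -> vector table ([read_embeddings()]).
#' @param config a [meddgtn_config()].
#' @return environment of class `meddgtn_model` holding the label graph,
#'   embeddings and all trainable parameters.
#' @export
meddgtn <- function(annotations, embeddings, config = meddgtn_config("test")) {
  assert_binary_matrix(annotations, "annotation matrix")
  labels <- colnames(annotations)
  if (is.null(labels)) stopf("annotation matrix needs label column names")
  vocab <- preprocess_labels(labels)
  H0 <- embed_labels(vocab, embeddings, seed = config$seed)
  g <- correlation_graph(annotations, tau = config$tau, p = config$p)
  N <- g$N
  if (config$graph_init == "cosine") {
    cs <- label_cosine_matrix(H0)
    Ncos <- reweight(binarize(pmax(cs, 0), config$tau), config$p)
    N <- (N + Ncos) / 2
  }
  C <- length(labels)
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$labels <- labels
  m$vocab <- vocab
  m$C <- C
  m$graphs <- g
  m$N <- N
  m$H0 <- H0
  m$backbone <- new_backbone(config$backbone, seed = config$seed)
  m$D <- config$backbone$final_channels
  m$dame <- dame_params(C, k = config$k, h = config$h, d_h = config$d_h,
                        seed = config$seed + 1L)
  m$gcn <- gcn_params(in_dim = ncol(H0), hidden = config$hidden, D = m$D,
                      seed = config$seed + 2L)
  class(m) <- "meddgtn_model"
  m
}

#' @export
print.meddgtn_model <- function(x, ...) {
  cat(sprintf("Med-DGTN model: %d labels, %s backbone (D = %d), k = %d subgraphs x %d heads (d_h = %d)\n",
              x$C, x$config$profile, x$D, x$config$k, x$config$h,
              x$config$d_h))
  invisible(x)
}

#' Current refined adjacency matrix of a model
#'
#' @param model a [meddgtn()] model.
#' @return row-normalised `C x C` adjacency `P` under the current attention
#'   parameters.
#' @export
model_adjacency <- function(model) dame_forward(model$N, model$dame)

.model_fwd <- function(model, images, train = FALSE, keep = FALSE) {
  dame <- .dame_fwd(model$N, model$dame)
  gcn <- .gcn_fwd(model$H0, dame$P, model$gcn)
  bb <- .backbone_fwd(model$backbone, images, train = train, keep = keep)
  if (train) model$backbone$buffers <- bb$buffers
  scores <- t(gcn$W %*% bb$x)            # n x C
  colnames(scores) <- model$labels
  list(scores = scores, x = bb$x, W = gcn$W,
       cache = if (keep) list(dame = dame$cache, gcn = gcn$cache,
                              bb = bb$cache, P = dame$P))
}

.model_bwd <- function(model, fwd, y) {
  n <- nrow(fwd$scores)
  dscores <- (sigmoid(fwd$scores) - y) / n
  dW <- t(dscores) %*% t(fwd$x)          # C x D
  dx <- t(fwd$W) %*% t(dscores)          # D x n
  g_bb <- .backbone_bwd(model$backbone, dx, fwd$cache$bb)
  g_gcn <- .gcn_bwd(dW, fwd$cache$gcn)
  g_dame <- .dame_bwd(g_gcn$dP, model$N, model$dame, fwd$cache$dame)
  list(cnn = g_bb,
       graph = list(gcn = list(W0 = g_gcn$dW0, W1 = g_gcn$dW1),
                    dame = g_dame))
}

#' Score images with a model
#'
#' Eval-mode forward pass (BN uses running statistics).
#'
#' @param model a [meddgtn()] model.
#' @param images `(3, S, S)` array or `(3, S, S, N)` batch.
#' @return `N x C` matrix of logits (1 x C for a single image).
#' @export
predict_scores <- function(model, images) {
  if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  .model_fwd(model, images, train = FALSE, keep = FALSE)$scores
}

# ---- structured parameter walking -------------------------------------------

# recursively apply f(param, grad-or-buddy) over two structurally identical
# nested lists of numeric arrays; named levels are aligned by name, so the
# two trees may list their components in different orders
.map2 <- function(a, b, f) {
  if (is.list(a)) {
    stopifnot(length(a) == length(b))
    out <- vector("list", length(a))
    names(out) <- names(a)
    nm <- names(a)
    by_name <- !is.null(nm) && !is.null(names(b)) && all(nzchar(nm)) &&
      !anyDuplicated(nm) && setequal(nm, names(b))
    for (i in seq_along(a)) {
      bi <- if (by_name) b[[nm[i]]] else b[[i]]
      out[[i]] <- .map2(a[[i]], bi, f)
    }
    return(out)
  }
  f(a, b)
}

.zeros_like <- function(a) {
  if (is.list(a)) return(lapply(a, .zeros_like))
  a * 0
}

.param_norm <- function(a) {
  if (is.list(a)) return(sum(vapply(a, .param_norm, numeric(1))))
  sum(a^2)
}

# one SGD-with-momentum step on a parameter tree; returns list(params, vel)
.sgd_step <- function(params, grads, vel, lr, momentum, wd) {
  new_vel <- .map2(.map2(params, grads, function(p, g) g + wd * p), vel,
                   function(gw, v) momentum * v + gw)
  list(params = .map2(params, new_vel, function(p, v) p - lr * v),
       vel = new_vel)
}

.model_param_groups <- function(model) {
  list(cnn = model$backbone$params,
       graph = list(gcn = model$gcn, dame = model$dame))
}

.model_set_params <- function(model, groups) {
  model$backbone$params <- groups$cnn
  model$gcn <- groups$graph$gcn
  model$dame <- groups$graph$dame
  invisible(model)
}

# align the gradient tree emitted by the backward passes with the parameter
# tree: dame gradients come back named dWq/dWk/dWv/dWo
.dame_grads_align <- function(g) {
  lapply(g, function(blk)
    list(heads = lapply(blk$dheads, function(h)
      list(Wq = h$dWq, Wk = h$dWk, Wv = h$dWv)),
      Wo = blk$dWo))
}

# ---- training ----------------------------------------------------------------

#' Train a model
#'
#' SGD with momentum, weight decay, two learning-rate groups (CNN branch vs
#' graph branch), multiplicative step decay of both rates every
#' `decay_every` epochs, and early stopping on the monitored mAP (validation
#' if given, else training) with best-weights restore. Fully seeded: two runs
#' with the same seed produce identical losses.
#'
#' @param model a [meddgtn()] model (modified in place; also returned).
#' @param dataset list with `images` (`(3, S, S, n)` array) and `y`
#'   (`n x C` binary matrix).
#' @param config a [train_config()].
#' @param validation optional list like `dataset` used for early stopping.
#' @param verbose print one line per epoch?
#' @return list with `model`, `log` (per-epoch data frame: loss, mAP of the
#'   monitored split), `best_epoch`, and `best_map`.
#' @export
train <- function(model, dataset, config = train_config(),
                  validation = NULL, verbose = FALSE) {
  if (is.null(dataset$images) || is.null(dataset$y) ||
      length(dim(dataset$images)) != 4L || dim(dataset$images)[4L] == 0L)
    stopf("dataset must provide a non-empty (3,S,S,n) image array and y matrix")
  n <- dim(dataset$images)[4L]
  if (nrow(dataset$y) != n) stopf("images and y disagree on sample count")
  log <- data.frame(epoch = integer(0), loss = numeric(0), mAP = numeric(0),
                    lr_graph = numeric(0), lr_cnn = numeric(0))
  best <- list(epoch = 0L, map = -Inf, groups = .model_param_groups(model),
               buffers = model$backbone$buffers)
  if (config$epochs == 0L)
    return(list(model = model, log = log, best_epoch = 0L, best_map = NA_real_))
  set.seed(config$seed)
  groups <- .model_param_groups(model)
  vel <- lapply(groups, .zeros_like)
  since_best <- 0L
  for (epoch in seq_len(config$epochs)) {
    fac <- config$decay_factor^((epoch - 1L) %/% config$decay_every)
    lr_g <- config$lr_graph * fac
    lr_c <- config$lr_cnn * fac
    idx <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      b <- idx[start:min(start + config$batch_size - 1L, n)]
      xb <- dataset$images[, , , b, drop = FALSE]
      yb <- dataset$y[b, , drop = FALSE]
      fwd <- .model_fwd(model, xb, train = TRUE, keep = TRUE)
      ep_loss <- ep_loss + bce_loss(fwd$scores, yb)
      g <- .model_bwd(model, fwd, yb)
      g$graph$dame <- .dame_grads_align(g$graph$dame)
      groups <- .model_param_groups(model)
      sc <- .sgd_step(groups$cnn, g$cnn, vel$cnn, lr_c,
                      config$momentum, config$weight_decay)
      sg <- .sgd_step(groups$graph, g$graph, vel$graph, lr_g,
                      config$momentum, config$weight_decay)
      vel <- list(cnn = sc$vel, graph = sg$vel)
      .model_set_params(model, list(cnn = sc$params, graph = sg$params))
      nb <- nb + 1L
    }
    mon <- if (is.null(validation)) dataset else validation
    scores <- predict_scores(model, mon$images)
    map <- as.numeric(mean_average_precision(scores, mon$y))
    log <- rbind(log, data.frame(epoch = epoch, loss = ep_loss / nb,
                                 mAP = map, lr_graph = lr_g, lr_cnn = lr_c))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  mAP %.2f", epoch,
                      ep_loss / nb, map))
    if (map > best$map) {
      best <- list(epoch = epoch, map = map,
                   groups = .model_param_groups(model),
                   buffers = model$backbone$buffers)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  .model_set_params(model, best$groups)
  model$backbone$buffers <- best$buffers
  list(model = model, log = log, best_epoch = best$epoch, best_map = best$map)
}

# ---- checkpoints -------------------------------------------------------------

.ckpt_version <- 1L

#' Save a model checkpoint
#'
#' Single-file binary checkpoint with a version field; round-trips through
#' [load_checkpoint()].
#'
#' @param model a [meddgtn()] model.
#' @param path output file.
#' @param epoch optional epoch number recorded for `--resume`-style use.
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_) {
  saveRDS(list(version = .ckpt_version, epoch = epoch,
               config = model$config, labels = model$labels,
               N = model$N, H0 = model$H0, graphs = model$graphs,
               backbone_params = model$backbone$params,
               backbone_buffers = model$backbone$buffers,
               dame = model$dame, gcn = model$gcn), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a restored `meddgtn_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(readRDS(path), error = function(e)
    stopf("cannot read checkpoint '%s': %s", path, conditionMessage(e)))
  if (!is.list(ck) || is.null(ck$version) || ck$version != .ckpt_version)
    stopf("corrupt or incompatible checkpoint: %s", path)
  m <- new.env(parent = emptyenv())
  m$config <- ck$config
  m$labels <- ck$labels
  m$C <- length(ck$labels)
  m$N <- ck$N
  m$H0 <- ck$H0
  m$graphs <- ck$graphs
  m$backbone <- structure(
    list(spec = ck$config$backbone, params = ck$backbone_params,
         buffers = ck$backbone_buffers),
    class = "meddgtn_backbone")
  m$D <- ck$config$backbone$final_channels
  m$dame <- ck$dame
  m$gcn <- ck$gcn
  m$epoch <- ck$epoch
  class(m) <- "meddgtn_model"
  m
}
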