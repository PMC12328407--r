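# Wavelet-convolution dense backbone.
#
# The image branch is a DenseNet-style network whose composite layers replace
# the plain 3x3 convolution with a wavelet convolution (WTConv): a depthwise
# base convolution plus a cascade that repeatedly decomposes the running
# low-frequency band with the orthonormal Haar transform, filters each of the
# four subbands with a small depthwise kernel, and reconstructs back up the
# cascade. Each decomposition level doubles the effective receptive field at
# the cost of only four extra small per-channel kernels, and the repeated
# processing of the LL band biases the operator toward the low spatial
# frequencies where anatomical and pathological structure lives.

#' Wavelet-convolution layer specification
#'
#' @param levels wavelet decomposition depth of the cascade (>= 1).
#' @param kernel spatial size of the small depthwise kernels (odd).
#' @param wavelet wavelet family; orthonormal Haar only.
#' @return object of class `wtconv_spec`.
#' @export
wtconv_spec <- function(levels = 2L, kernel = 3L, wavelet = "haar") {
  levels <- as.integer(levels); kernel <- as.integer(kernel)
  if (levels < 1L) stopf("levels must be >= 1")
  if (kernel %% 2L == 0L) stopf("kernel size must be odd")
  .check_haar(wavelet)
  structure(list(levels = levels, kernel = kernel, wavelet = wavelet),
            class = "wtconv_spec")
}

#' Initialise wavelet-convolution parameters
#'
#' One depthwise base kernel plus, per cascade level, four depthwise subband
#' kernels (`LL`, `LH`, `HL`, `HH`), all of shape `channels x kernel x kernel`.
#'
#' @param channels number of feature channels the layer operates on.
#' @param spec a [wtconv_spec()].
#' @param init `"he"` (scaled random, draws from the current RNG stream),
#'   `"dirac"` (identity kernels: the layer returns twice its input), or
#'   `"zero"`.
#' @return named list of kernel arrays.
#' @export
wtconv_params <- function(channels, spec = wtconv_spec(), init = "he") {
  k <- spec$kernel
  mk <- function() {
    w <- array(0, c(channels, k, k))
    if (init == "he") {
      w[] <- stats::rnorm(length(w), sd = sqrt(2 / (k * k)))
    } else if (init == "dirac") {
      w[, (k + 1L) %/% 2L, (k + 1L) %/% 2L] <- 1
    } else if (init != "zero") stopf("unknown init '%s'", init)
    w
  }
  p <- list(base = mk())
  for (l in seq_len(spec$levels))
    p[[paste0("l", l)]] <- list(LL = mk(), LH = mk(), HL = mk(), HH = mk())
  p
}

.wtconv_fwd <- function(x, spec, params, keep = TRUE) {
  d <- dim(x)
  if (min(d[2L], d[3L]) < 2^spec$levels)
    stopf("spatial dims %dx%d too small for %d wavelet levels",
          d[2L], d[3L], spec$levels)
  base <- .dwconv_fwd(x, params$base)
  L <- spec$levels
  run <- x
  s_list <- vector("list", L); conv_caches <- vector("list", L)
  conv_out <- vector("list", L)
  for (l in seq_len(L)) {
    s <- .dwt4(run)
    cl <- lapply(c("LL", "LH", "HL", "HH"), function(b)
      .dwconv_fwd(s[[b]], params[[paste0("l", l)]][[b]]))
    names(cl) <- c("LL", "LH", "HL", "HH")
    s_list[[l]] <- list(H = s$H, W = s$W,
                        sub_h = dim(s$LL)[2L], sub_w = dim(s$LL)[3L])
    conv_caches[[l]] <- lapply(cl, `[[`, "cache")
    conv_out[[l]] <- lapply(cl, `[[`, "out")
    run <- conv_out[[l]]$LL
  }
  rec <- conv_out[[L]]$LL
  for (l in rev(seq_len(L))) {
    rec <- .idwt4(list(LL = rec, LH = conv_out[[l]]$LH,
                       HL = conv_out[[l]]$HL, HH = conv_out[[l]]$HH,
                       H = s_list[[l]]$H, W = s_list[[l]]$W))
  }
  out <- base$out + rec
  cache <- if (keep)
    list(base = base$cache, s = s_list, conv = conv_caches, L = L, in_dim = d)
  list(out = out, cache = cache)
}

.wtconv_bwd <- function(dout, cache) {
  L <- cache$L
  g_base <- .dwconv_bwd(dout, cache$base)
  dW <- list(base = g_base$dW)
  # down the reconstruction: split the cascade gradient into per-level
  # convolved-subband gradients (the LL slot carries the deeper level)
  dconv <- vector("list", L)
  drec <- dout
  for (l in seq_len(L)) {
    S <- .idwt4_adj(drec, cache$s[[l]]$sub_h, cache$s[[l]]$sub_w)
    dconv[[l]] <- list(LH = S$LH, HL = S$HL, HH = S$HH)
    drec <- S$LL
  }
  dcll_deep <- drec
  # up the decomposition: convert subband gradients into the gradient of the
  # running low-frequency band one level up
  drun <- NULL
  for (l in rev(seq_len(L))) {
    dcll <- if (l == L) dcll_deep else drun
    gs <- list()
    lev <- list()
    for (b in c("LL", "LH", "HL", "HH")) {
      gin <- if (b == "LL") dcll else dconv[[l]][[b]]
      g <- .dwconv_bwd(gin, cache$conv[[l]][[b]])
      gs[[b]] <- g$dx
      lev[[b]] <- g$dW
    }
    dW[[paste0("l", l)]] <- lev
    up_h <- if (l == 1L) cache$in_dim[2L] else cache$s[[l - 1L]]$sub_h
    up_w <- if (l == 1L) cache$in_dim[3L] else cache$s[[l - 1L]]$sub_w
    drun <- .dwt4_adj(gs, up_h, up_w)
  }
  list(dx = g_base$dx + drun, dW = dW)
}

#' Apply a wavelet convolution
#'
#' Channel- and shape-preserving. With `init = "dirac"` kernels the base path
#' reproduces the input and the cascade reconstructs it exactly, so the output
#' equals twice the input -- a useful round-trip check of the transform
#' plumbing.
#'
#' @param feature array `(C, H, W)` or `(C, H, W, N)`.
#' @param spec a [wtconv_spec()].
#' @param params kernels from [wtconv_params()].
#' @return array of the same shape as `feature`.
#' @export
wtconv <- function(feature, spec = wtconv_spec(), params) {
  x <- if (length(dim(feature)) == 3L)
    array(feature, c(dim(feature), 1L)) else feature
  out <- .wtconv_fwd(x, spec, params, keep = FALSE)$out
  if (length(dim(feature)) == 3L) array(out, dim(feature)) else out
}

# ---- dense block -------------------------------------------------------------

#' Dense-block specification
#'
#' @param num_layers composite layers per block (each BN -> ReLU -> 1x1
#'   channel-mapping conv -> depthwise WTConv); the reference layout uses six.
#' @param growth channels contributed by each composite layer.
#' @return object of class `wtdense_spec`.
#' @export
wtdense_spec <- function(num_layers = 6L, growth = 48L) {
  num_layers <- as.integer(num_layers); growth <- as.integer(growth)
  if (num_layers < 1L) stopf("num_layers must be >= 1")
  if (growth < 1L) stopf("growth must be >= 1")
  structure(list(num_layers = num_layers, growth = growth),
            class = "wtdense_spec")
}

.wtdense_layer_params <- function(cin, growth, wt_spec, init = "he") {
  gain <- sqrt(2 / cin)
  list(bn.g = rep(1, cin), bn.b = rep(0, cin),
       proj.W = array(stats::rnorm(growth * cin, sd = gain) *
                        (init == "he"), c(growth, cin, 1L, 1L)),
       wt = wtconv_params(growth, wt_spec, init = init))
}

.wtdense_layer_buffers <- function(cin) list(rm = rep(0, cin), rv = rep(1, cin))

.wtdense_block_fwd <- function(x, spec, wt_spec, params, buffers,
                               train = FALSE, keep = TRUE) {
  caches <- vector("list", spec$num_layers)
  run <- x
  for (j in seq_len(spec$num_layers)) {
    pj <- params[[j]]; bj <- buffers[[j]]
    bn <- .bn_fwd(run, pj$bn.g, pj$bn.b, bj$rm, bj$rv, train = train)
    buffers[[j]] <- list(rm = bn$running_mean, rv = bn$running_var)
    rl <- .relu_fwd(bn$out)
    pr <- .conv2d_fwd(rl$out, pj$proj.W)
    wt <- .wtconv_fwd(pr$out, wt_spec, pj$wt, keep = keep)
    if (keep)
      caches[[j]] <- list(bn = bn$cache, relu = rl$cache, proj = pr$cache,
                          wt = wt$cache, cin = dim(run)[1L])
    run <- .concat_c(run, wt$out)
  }
  list(out = run, caches = caches, buffers = buffers)
}

.concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L] + db[1L], da[2L], da[3L], da[4L]))
  out[seq_len(da[1L]), , , ] <- a
  out[da[1L] + seq_len(db[1L]), , , ] <- b
  out
}

.wtdense_block_bwd <- function(dout, spec, params, caches) {
  grads <- vector("list", spec$num_layers)
  drun <- dout
  for (j in rev(seq_len(spec$num_layers))) {
    cj <- caches[[j]]
    cin <- cj$cin
    d_in <- drun[seq_len(cin), , , , drop = FALSE]
    d_new <- drun[-seq_len(cin), , , , drop = FALSE]
    gwt <- .wtconv_bwd(d_new, cj$wt)
    gpr <- .conv2d_bwd(gwt$dx, cj$proj)
    drl <- .relu_bwd(gpr$dx, cj$relu)
    gbn <- .bn_bwd(drl, cj$bn)
    grads[[j]] <- list(bn.g = gbn$dgamma, bn.b = gbn$dbeta,
                       proj.W = gpr$dW, wt = gwt$dW)
    drun <- d_in + gbn$dx
  }
  list(dx = drun, grads = grads)
}

#' Run a WTDense block
#'
#' Applies `num_layers` composite layers (BN -> ReLU -> 1x1 conv to `growth`
#' channels -> depthwise WTConv), concatenating each layer's output onto the
#' running feature stack, so the channel count grows from `C_in` to
#' `C_in + num_layers * growth` while the spatial dimensions are unchanged.
#'
#' @param feature array `(C, H, W)` or `(C, H, W, N)`.
#' @param spec a [wtdense_spec()].
#' @param params list of per-layer parameter lists (see
#'   [wtdense_block_params()]).
#' @param wt_spec a [wtconv_spec()].
#' @return array with `C_in + num_layers * growth` channels.
#' @export
wtdense_block <- function(feature, spec = wtdense_spec(), params,
                          wt_spec = wtconv_spec()) {
  x <- if (length(dim(feature)) == 3L)
    array(feature, c(dim(feature), 1L)) else feature
  cin <- dim(x)[1L]
  buffers <- list()
  run_c <- cin
  for (j in seq_len(spec$num_layers)) {
    buffers[[j]] <- .wtdense_layer_buffers(run_c)
    run_c <- run_c + spec$growth
  }
  out <- .wtdense_block_fwd(x, spec, wt_spec, params, buffers,
                            train = TRUE, keep = FALSE)$out
  if (length(dim(feature)) == 3L) array(out, dim(out)[1:3]) else out
}

#' Initialise parameters for a WTDense block
#'
#' @param cin input channel count.
#' @param spec a [wtdense_spec()].
#' @param wt_spec a [wtconv_spec()].
#' @param init kernel initialisation passed to [wtconv_params()].
#' @return list with one parameter list per composite layer.
#' @export
wtdense_block_params <- function(cin, spec = wtdense_spec(),
                                 wt_spec = wtconv_spec(), init = "he") {
  p <- vector("list", spec$num_layers)
  run_c <- cin
  for (j in seq_len(spec$num_layers)) {
    p[[j]] <- .wtdense_layer_params(run_c, spec$growth, wt_spec, init = init)
    run_c <- run_c + spec$growth
  }
  p
}

# ---- transition --------------------------------------------------------------

.transition_fwd <- function(x, params, buffers, train = FALSE, keep = TRUE) {
  bn <- .bn_fwd(x, params$bn.g, params$bn.b, buffers$rm, buffers$rv,
                train = train)
  rl <- .relu_fwd(bn$out)
  pr <- .conv2d_fwd(rl$out, params$W)
  ap <- .avgpool2_fwd(pr$out)
  cache <- if (keep) list(bn = bn$cache, relu = rl$cache, proj = pr$cache,
                          pool = ap$cache)
  list(out = ap$out, cache = cache,
       buffers = list(rm = bn$running_mean, rv = bn$running_var))
}

.transition_bwd <- function(dout, cache) {
  dap <- .avgpool2_bwd(dout, cache$pool)
  gpr <- .conv2d_bwd(dap, cache$proj)
  drl <- .relu_bwd(gpr$dx, cache$relu)
  gbn <- .bn_bwd(drl, cache$bn)
  list(dx = gbn$dx, grads = list(bn.g = gbn$dgamma, bn.b = gbn$dbeta,
                                 W = gpr$dW))
}

#' Transition layer: 1x1 channel compression + 2x2 average pooling
#'
#' Halves the spatial dimensions (odd dimensions are replicate-padded first)
#' and compresses channels by the factor `theta`.
#'
#' @param feature array `(C, H, W)` or `(C, H, W, N)`.
#' @param params parameter list from [transition_params()]; if missing, an
#'   identity 1x1 kernel with `theta = 1` is used so the output is the exact
#'   2x2 block mean of the input.
#' @param theta channel compression factor in (0, 1]; used only when `params`
#'   is missing.
#' @return array with halved spatial dimensions.
#' @export
transition <- function(feature, params = NULL, theta = 1) {
  x <- if (length(dim(feature)) == 3L)
    array(feature, c(dim(feature), 1L)) else feature
  cin <- dim(x)[1L]
  if (is.null(params)) {
    if (theta != 1) stopf("supply params for theta != 1")
    W <- array(0, c(cin, cin, 1L, 1L)); W[cbind(1:cin, 1:cin, 1L, 1L)] <- 1
    # identity path: skip BN/ReLU so the block-mean contract is exact
    pr <- .conv2d_fwd(x, W)
    out <- .avgpool2_fwd(pr$out)$out
  } else {
    out <- .transition_fwd(x, params, .wtdense_layer_buffers(cin),
                           train = TRUE, keep = FALSE)$out
  }
  if (length(dim(feature)) == 3L) array(out, dim(out)[1:3]) else out
}

#' Initialise transition-layer parameters
#' @param cin input channel count.
#' @param theta channel compression factor in (0, 1].
#' @return parameter list (`bn.g`, `bn.b`, `W`).
#' @export
transition_params <- function(cin, theta = 0.5) {
  if (theta <= 0 || theta > 1) stopf("theta must be in (0, 1]")
  cout <- max(1L, as.integer(floor(cin * theta)))
  list(bn.g = rep(1, cin), bn.b = rep(0, cin),
       W = array(stats::rnorm(cout * cin, sd = sqrt(2 / cin)),
                 c(cout, cin, 1L, 1L)))
}

# ---- full backbone -----------------------------------------------------------

#' Backbone specification
#'
#' The default profile mirrors the reference layout: a 448x448 input, a 7x7
#' stride-2 stem convolution plus 3x3 stride-2 max pooling, four WTDense
#' blocks of six composite layers (growth 48) separated by three transition
#' layers (theta = 0.5), and a final 1x1 projection to `final_channels = 2048`
#' so the pre-pool map is 2048 x 14 x 14. The `"test"` profile is a
#' proportionally shallower 112x112 variant for desk-scale experiments.
#'
#' @param profile `"default"` (448-input reference layout) or `"test"`
#'   (112-input reduced layout).
#' @param input_size,stem_channels,num_blocks,num_layers,growth,theta,
#'   final_channels,levels optional overrides of the profile values.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(profile = c("default", "test"),
                          input_size = NULL, stem_channels = NULL,
                          num_blocks = NULL, num_layers = NULL,
                          growth = NULL, theta = NULL,
                          final_channels = NULL, levels = NULL) {
  profile <- match.arg(profile)
  base <- if (profile == "default") {
    list(input_size = 448L, stem_channels = 64L, num_blocks = 4L,
         num_layers = 6L, growth = 48L, theta = 0.5, final_channels = 2048L,
         levels = 2L)
  } else {
    list(input_size = 112L, stem_channels = 16L, num_blocks = 4L,
         num_layers = 2L, growth = 8L, theta = 0.5, final_channels = 128L,
         levels = 1L)
  }
  ov <- list(input_size = input_size, stem_channels = stem_channels,
             num_blocks = num_blocks, num_layers = num_layers,
             growth = growth, theta = theta, final_channels = final_channels,
             levels = levels)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) base[[nm]] <- ov[[nm]]
  base$profile <- profile
  base$wt <- wtconv_spec(levels = base$levels)
  base$block <- wtdense_spec(num_layers = base$num_layers,
                             growth = base$growth)
  structure(base, class = "backbone_spec")
}

#' Build a backbone with freshly initialised parameters
#'
#' @param spec a [backbone_spec()].
#' @param seed integer seed for the parameter draws.
#' @return object of class `meddgtn_backbone`: `spec` plus nested `params`
#'   and `buffers` lists.
#' @export
new_backbone <- function(spec = backbone_spec(), seed = 1L) {
  with_seed(seed, {
    sc <- spec$stem_channels
    params <- list(
      stem.W = array(stats::rnorm(sc * 3 * 49, sd = sqrt(2 / (3 * 49))),
                     c(sc, 3L, 7L, 7L)),
      stem.b = rep(0, sc),
      stem.bn = list(g = rep(1, sc), b = rep(0, sc))
    )
    buffers <- list(stem.bn = list(rm = rep(0, sc), rv = rep(1, sc)))
    run_c <- sc
    params$blocks <- vector("list", spec$num_blocks)
    params$trans <- vector("list", spec$num_blocks - 1L)
    buffers$blocks <- vector("list", spec$num_blocks)
    for (bi in seq_len(spec$num_blocks)) {
      params$blocks[[bi]] <- wtdense_block_params(run_c, spec$block, spec$wt)
      buffers$blocks[[bi]] <- lapply(
        run_c + spec$growth * (seq_len(spec$num_layers) - 1L),
        .wtdense_layer_buffers)
      run_c <- run_c + spec$num_layers * spec$growth
      if (bi < spec$num_blocks) {
        params$trans[[bi]] <- transition_params(run_c, spec$theta)
        buffers$trans[[bi]] <- .wtdense_layer_buffers(run_c)
        run_c <- max(1L, as.integer(floor(run_c * spec$theta)))
      }
    }
    params$final <- list(
      bn.g = rep(1, run_c), bn.b = rep(0, run_c),
      W = array(stats::rnorm(spec$final_channels * run_c,
                             sd = sqrt(2 / run_c)),
                c(spec$final_channels, run_c, 1L, 1L)))
    buffers$final <- .wtdense_layer_buffers(run_c)
    structure(list(spec = spec, params = params, buffers = buffers,
                   pre_final_channels = run_c),
              class = "meddgtn_backbone")
  })
}

.backbone_fwd <- function(bb, x, train = FALSE, keep = TRUE) {
  spec <- bb$spec; p <- bb$params; buf <- bb$buffers
  d <- dim(x)
  if (d[1L] != 3L || d[2L] != spec$input_size || d[3L] != spec$input_size)
    stopf("backbone expects 3x%dx%d input, got %dx%dx%d",
          spec$input_size, spec$input_size, d[1L], d[2L], d[3L])
  stem <- .conv2d_fwd(x, p$stem.W, p$stem.b, stride = 2L)
  bns <- .bn_fwd(stem$out, p$stem.bn$g, p$stem.bn$b,
                 buf$stem.bn$rm, buf$stem.bn$rv, train = train)
  buf$stem.bn <- list(rm = bns$running_mean, rv = bns$running_var)
  rls <- .relu_fwd(bns$out)
  mp <- .maxpool_fwd(rls$out)
  run <- mp$out
  bcaches <- vector("list", spec$num_blocks)
  tcaches <- vector("list", spec$num_blocks - 1L)
  for (bi in seq_len(spec$num_blocks)) {
    bf <- .wtdense_block_fwd(run, spec$block, spec$wt, p$blocks[[bi]],
                             buf$blocks[[bi]], train = train, keep = keep)
    buf$blocks[[bi]] <- bf$buffers
    bcaches[[bi]] <- bf$caches
    run <- bf$out
    if (bi < spec$num_blocks) {
      tf <- .transition_fwd(run, p$trans[[bi]], buf$trans[[bi]],
                            train = train, keep = keep)
      buf$trans[[bi]] <- tf$buffers
      tcaches[[bi]] <- tf$cache
      run <- tf$out
    }
  }
  bnf <- .bn_fwd(run, p$final$bn.g, p$final$bn.b,
                 buf$final$rm, buf$final$rv, train = train)
  buf$final <- list(rm = bnf$running_mean, rv = bnf$running_var)
  rlf <- .relu_fwd(bnf$out)
  prf <- .conv2d_fwd(rlf$out, p$final$W)
  prepool_hw <- dim(prf$out)[2:3]
  gp <- .gap_fwd(prf$out)
  cache <- if (keep)
    list(stem = stem$cache, stem_bn = bns$cache, stem_relu = rls$cache,
         mp = mp$cache, blocks = bcaches, trans = tcaches,
         final_bn = bnf$cache, final_relu = rlf$cache, final_proj = prf$cache,
         gap = gp$cache)
  list(x = gp$out, prepool_hw = prepool_hw, cache = cache, buffers = buf)
}

.backbone_bwd <- function(bb, dx_feat, cache) {
  spec <- bb$spec
  g <- list()
  dmap <- .gap_bwd(dx_feat, cache$gap)
  gprf <- .conv2d_bwd(dmap, cache$final_proj)
  drlf <- .relu_bwd(gprf$dx, cache$final_relu)
  gbnf <- .bn_bwd(drlf, cache$final_bn)
  g$final <- list(bn.g = gbnf$dgamma, bn.b = gbnf$dbeta, W = gprf$dW)
  drun <- gbnf$dx
  g$blocks <- vector("list", spec$num_blocks)
  g$trans <- vector("list", spec$num_blocks - 1L)
  for (bi in rev(seq_len(spec$num_blocks))) {
    if (bi < spec$num_blocks) {
      gt <- .transition_bwd(drun, cache$trans[[bi]])
      g$trans[[bi]] <- gt$grads
      drun <- gt$dx
    }
    gb <- .wtdense_block_bwd(drun, spec$block, bb$params$blocks[[bi]],
                             cache$blocks[[bi]])
    g$blocks[[bi]] <- gb$grads
    drun <- gb$dx
  }
  dmp <- .maxpool_bwd(drun, cache$mp)
  drls <- .relu_bwd(dmp, cache$stem_relu)
  gbns <- .bn_bwd(drls, cache$stem_bn)
  g$stem.bn <- list(g = gbns$dgamma, b = gbns$dbeta)
  gstem <- .conv2d_bwd(gbns$dx, cache$stem)
  g$stem.W <- gstem$dW
  g$stem.b <- gstem$db
  g
}

#' Extract the pooled image feature
#'
#' Runs one or more images through the backbone: 7x7 stride-2 stem
#' convolution, 3x3 stride-2 max pooling, the WTDense blocks and transition
#' layers, a final 1x1 projection to `final_channels`, and global average
#' pooling. For the default 448-input profile the pre-pool map is
#' `final_channels x 14 x 14` and the pooled feature has length 2048.
#'
#' @param backbone a [new_backbone()] object.
#' @param images array `(3, S, S)` for one image or `(3, S, S, N)` for a
#'   batch, where `S` is the configured input size.
#' @param train logical; `TRUE` uses batch statistics in the BN layers.
#' @return a length-`final_channels` numeric vector (single image) or a
#'   `final_channels x N` matrix, with attribute `"prepool_hw"` giving the
#'   spatial size of the map entering global average pooling.
#' @export
backbone_forward <- function(backbone, images, train = FALSE) {
  single <- length(dim(images)) == 3L
  x <- if (single) array(images, c(dim(images), 1L)) else images
  f <- .backbone_fwd(backbone, x, train = train, keep = FALSE)
  out <- if (single) drop(f$x) else f$x
  attr(out, "prepool_hw") <- f$prepool_hw
  out
}
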