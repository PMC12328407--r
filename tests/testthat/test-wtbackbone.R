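test_that("wtconv with identity kernels reproduces the input twice over", {
  set.seed(3)
  x <- array(rnorm(2 * 16 * 16), c(2, 16, 16))
  for (lev in 1:2) {
    sp <- wtconv_spec(levels = lev)
    out <- wtconv(x, sp, wtconv_params(2L, sp, init = "dirac"))
    # base path reproduces x, the cascade reconstructs x exactly
    expect_lt(max(abs(out - 2 * x)), 1e-4)
  }
  sp <- wtconv_spec(levels = 2)
  expect_equal(max(abs(wtconv(x, sp, wtconv_params(2L, sp, init = "zero")))), 0)
})

test_that("wtconv matches a from-scratch subband oracle (ramp, level 1)", {
  set.seed(4)
  S <- 12L
  ramp <- matrix(seq(0, 1, length.out = S * S), S, S)
  sp <- wtconv_spec(levels = 1)
  p <- wtconv_params(1L, sp, init = "he")
  got <- wtconv(array(ramp, c(1, S, S)), sp, p)[1, , ]
  # oracle: dwt2 -> per-subband naive 3x3 correlation -> idwt2, + base conv
  s <- dwt2(ramp)
  rec <- idwt2(list(LL = ref_conv2d(s$LL, matrix(p$l1$LL[1, , ], 3, 3)),
                    LH = ref_conv2d(s$LH, matrix(p$l1$LH[1, , ], 3, 3)),
                    HL = ref_conv2d(s$HL, matrix(p$l1$HL[1, , ], 3, 3)),
                    HH = ref_conv2d(s$HH, matrix(p$l1$HH[1, , ], 3, 3))))
  want <- ref_conv2d(ramp, matrix(p$base[1, , ], 3, 3)) + rec
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("wtconv preserves channel count and spatial dims", {
  set.seed(5)
  for (d in list(c(3L, 8L, 8L), c(5L, 14L, 14L), c(2L, 9L, 11L))) {
    sp <- wtconv_spec(levels = 1)
    x <- array(rnorm(prod(d)), d)
    expect_identical(dim(wtconv(x, sp, wtconv_params(d[1L], sp))), d)
  }
  sp2 <- wtconv_spec(levels = 3)
  expect_error(wtconv(array(0, c(1, 4, 4)), sp2, wtconv_params(1L, sp2)),
               "too small")
})

test_that("dense block concatenates its composite layers' channels", {
  set.seed(6)
  sp <- wtdense_spec(num_layers = 2L, growth = 4L)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  out <- wtdense_block(x, sp, wtdense_block_params(8L, sp, wtconv_spec(1)),
                       wt_spec = wtconv_spec(1))
  expect_identical(dim(out), c(16L, 8L, 8L))
  expect_error(wtdense_spec(num_layers = 0L), "num_layers")
  # the reference layout uses six composite layers
  expect_identical(wtdense_spec()$num_layers, 6L)
  expect_identical(backbone_spec("default")$num_layers, 6L)
})

test_that("transition halves spatial dims and computes exact block means", {
  x <- array(rnorm(2 * 28 * 28), c(2, 28, 28))
  out <- transition(x)
  expect_identical(dim(out), c(2L, 14L, 14L))
  # constant map stays constant under average pooling
  expect_equal(max(abs(transition(array(2.5, c(1, 8, 8))) - 2.5)), 0)
  # identity 1x1 kernels, theta = 1: exact 2x2 block means
  m <- matrix(rnorm(36), 6, 6)
  got <- transition(array(m, c(1, 6, 6)))[1, , ]
  want <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    want[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(got, want)
})

test_that("backbone forward meets its shape contracts", {
  bb <- new_backbone(backbone_spec("test"), seed = 2)
  set.seed(7)
  img <- array(runif(3 * 112 * 112), c(3, 112, 112))
  f <- backbone_forward(bb, img)
  expect_length(f, 128L)
  expect_true(all(is.finite(f)))
  # batched input gives one column per image
  batch <- array(runif(3 * 112 * 112 * 2), c(3, 112, 112, 2))
  fb <- backbone_forward(bb, batch)
  expect_identical(dim(fb), c(128L, 2L))
  expect_error(backbone_forward(bb, array(0, c(3, 64, 64))), "3x112x112")
})

test_that("a zero image propagates to a zero pooled feature in eval mode", {
  # zero-init stem bias, identity-affine BN with fresh running stats: every
  # layer maps zero to zero, so the pooled feature is exactly zero
  bb <- new_backbone(backbone_spec("test"), seed = 3)
  img <- array(0, c(3, 112, 112))
  f1 <- backbone_forward(bb, img)
  expect_equal(max(abs(f1)), 0)
  expect_identical(as.numeric(f1), as.numeric(backbone_forward(bb, img)))
})

test_that("the LL path responds more to low-frequency input than high", {
  # equal-energy broad Gaussian vs checkerboard through a level-2 cascade:
  # the twice-decomposed LL band must carry more energy for the Gaussian
  S <- 32L
  yy <- matrix(seq_len(S), S, S); xx <- t(yy)
  gauss <- exp(-((yy - S / 2)^2 + (xx - S / 2)^2) / (2 * (S / 4)^2))
  checker <- matrix(rep_len(c(1, -1), S * S), S, S) *
    matrix(rep(rep_len(c(1, -1), S), each = S), S, S)
  checker <- checker * sqrt(sum(gauss^2) / sum(checker^2))
  ll2 <- function(m) {
    s1 <- dwt2(m); s2 <- dwt2(s1$LL); sum(s2$LL^2)
  }
  expect_gt(ll2(gauss), ll2(checker))
  # and through seeded random wtconv kernels the cascade output energy
  # ordering is preserved
  set.seed(8)
  sp <- wtconv_spec(levels = 2)
  p <- wtconv_params(1L, sp)
  p$base[] <- 0                        # isolate the cascade path
  e_low <- sum(wtconv(array(gauss, c(1, S, S)), sp, p)^2)
  e_high <- sum(wtconv(array(checker, c(1, S, S)), sp, p)^2)
  expect_gt(e_low, e_high)
})

test_that("backbone parameter gradients match finite differences", {
  fx <- tiny_model(seed = 21L, n = 3L)
  m <- fx$model
  # move the attention output projections off zero: at Wo = 0 the rectifier
  # sits exactly on its kink for the graph's structural zeros, where the
  # subgradient and a finite difference legitimately disagree
  set.seed(22)
  for (j in seq_along(m$dame))
    m$dame[[j]]$Wo <- matrix(rnorm(length(m$dame[[j]]$Wo), sd = 0.05),
                             nrow(m$dame[[j]]$Wo))
  x <- fx$dataset$images[, , , 1:2, drop = FALSE]
  y <- fx$dataset$y[1:2, , drop = FALSE]
  fwd <- meddgtn:::.model_fwd(m, x, train = TRUE, keep = TRUE)
  g <- meddgtn:::.model_bwd(m, fwd, y)
  loss_at <- function()
    bce_loss(meddgtn:::.model_fwd(m, x, train = TRUE, keep = FALSE)$scores, y)
  eps <- 1e-5
  check_one <- function(get, set, gval) {
    p0 <- get()
    i <- which.max(abs(gval))          # probe the steepest coordinate
    p <- p0; p[i] <- p0[i] + eps; set(p); lp <- loss_at()
    p[i] <- p0[i] - eps; set(p); lm <- loss_at(); set(p0)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - gval[i]) / max(1e-6, abs(num) + abs(gval[i])), 1e-4)
  }
  check_one(function() m$backbone$params$stem.W,
            function(p) m$backbone$params$stem.W <- p, g$cnn$stem.W)
  check_one(function() m$backbone$params$blocks[[1]][[1]]$wt$base,
            function(p) m$backbone$params$blocks[[1]][[1]]$wt$base <- p,
            g$cnn$blocks[[1]][[1]]$wt$base)
  check_one(function() m$backbone$params$trans[[1]]$W,
            function(p) m$backbone$params$trans[[1]]$W <- p,
            g$cnn$trans[[1]]$W)
  check_one(function() m$gcn$W1, function(p) m$gcn$W1 <- p, g$graph$gcn$W1)
  check_one(function() m$dame[[1]]$Wo, function(p) m$dame[[1]]$Wo <- p,
            g$graph$dame[[1]]$dWo)
})
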