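test_that("co-occurrence counting matches direct pair enumeration", {
  ann <- rbind(c(1, 1), c(1, 0), c(0, 1))
  colnames(ann) <- c("a", "b")
  expect_equal(unname(count_cooccurrence(ann)),
               matrix(c(2, 1, 1, 2), 2, 2))
  # all-zero annotations give all-zero counts
  z <- matrix(0, 5, 3); colnames(z) <- c("x", "y", "z")
  expect_equal(unname(count_cooccurrence(z)), matrix(0, 3, 3))
  # planted 2-block model: recount by brute-force pair enumeration
  spec <- synth_spec(C = 4L, n = 200L, blocks = 2L, p_within = 0.6,
                     p_between = 0.05, seed = 31L)
  y <- sample_labels(spec)
  M <- count_cooccurrence(y)
  brute <- matrix(0, 4, 4)
  for (s in seq_len(nrow(y)))
    for (i in 1:4) for (j in 1:4)
      brute[i, j] <- brute[i, j] + (y[s, i] == 1 && y[s, j] == 1)
  expect_equal(unname(M), brute)
  within <- c(M[1, 2], M[3, 4]); between <- c(M[1, 3], M[1, 4], M[2, 3], M[2, 4])
  expect_gt(mean(within), mean(between))
})

test_that("co-occurrence is symmetric with per-label totals on the diagonal", {
  # exhaustive over all 3x4 binary matrices (2^12 cases)
  ok_sym <- ok_diag <- ok_bound <- TRUE
  for (code in 0:(2^12 - 1)) {
    y <- matrix(as.integer(intToBits(code))[1:12], 3, 4)
    M <- count_cooccurrence(y)
    ok_sym <- ok_sym && isSymmetric(unname(M))
    ok_diag <- ok_diag && all(diag(M) == colSums(y))
    ok_bound <- ok_bound && all(M <= pmin(outer(diag(M), rep(1, 4)),
                                          outer(rep(1, 4), diag(M))))
  }
  expect_true(ok_sym)
  expect_true(ok_diag)
  expect_true(ok_bound)
  expect_error(count_cooccurrence(matrix(c(0, 2), 1, 2)), "0/1")
  expect_error(count_cooccurrence(matrix(numeric(0), 0, 2)), "row")
})

test_that("conditional probabilities are row-conditioned counts", {
  expect_equal(conditional_probabilities(matrix(c(10, 4, 4, 5), 2, 2)),
               matrix(c(1.0, 0.8, 0.4, 1.0), 2, 2))
  # diagonal-only counts give the identity
  expect_equal(conditional_probabilities(diag(c(3, 7, 2))), diag(3))
  # zero-occurrence labels become isolated self-loop nodes
  M0 <- matrix(c(4, 0, 0, 0), 2, 2)
  expect_equal(conditional_probabilities(M0), diag(2))
  # planted-block counts against the element-wise division oracle
  spec <- synth_spec(C = 4L, n = 150L, seed = 32L)
  M <- count_cooccurrence(sample_labels(spec))
  Mp <- conditional_probabilities(M)
  for (i in 1:4) expect_equal(unname(Mp[i, ]), unname(M[i, ] / M[i, i]))
  expect_false(isSymmetric(unname(Mp)))   # conditioning is directional
})

test_that("binarize thresholds exactly and monotonically", {
  Mp <- matrix(c(1.0, 0.39, 0.4, 1.0), 2, 2)
  expect_equal(binarize(Mp, 0.4), matrix(c(1, 0, 1, 1), 2, 2))
  expect_equal(binarize(Mp, 0), matrix(1, 2, 2))   # everything >= 0
  set.seed(33)
  R <- matrix(runif(36), 6, 6)
  expect_equal(binarize(R, 0.5), (R >= 0.5) * 1)
  # monotone: raising tau never adds an edge
  taus <- sort(runif(5))
  for (t in seq_along(taus)[-1])
    expect_true(all(binarize(R, taus[t]) <= binarize(R, taus[t - 1])))
  expect_error(binarize(R, 1.2), "tau")
  expect_error(binarize(R, -0.1), "tau")
})

test_that("reweighting balances self-loops against neighbour mass", {
  A <- matrix(c(1, 1, 0,
                1, 1, 1,
                0, 1, 1), 3, 3, byrow = TRUE)
  N <- reweight(A, p = 0.2)
  expect_equal(diag(N), rep(0.8, 3))
  expect_equal(N[1, 2], 0.2)           # row 1 has one neighbour
  expect_equal(N[2, 1], 0.1)           # row 2 splits p over two neighbours
  expect_equal(N[2, 3], 0.1)
  # p = 0 gives the identity: the self-connection dominates
  expect_equal(reweight(A, 0), diag(3))
  # off-diagonal row mass is p for every non-isolated node
  set.seed(34)
  A2 <- matrix(rbinom(64, 1, 0.4), 8, 8)
  N2 <- reweight(A2, 0.5)
  off <- rowSums(N2) - diag(N2)
  iso <- rowSums(A2 * (1 - diag(8))) == 0
  expect_equal(off[!iso], rep(0.5, sum(!iso)))
  expect_equal(off[iso], rep(0, sum(iso)))
  expect_error(reweight(A, 1.5), "p")
})

test_that("attention heads are row-stochastic and match dense algebra", {
  C <- 3L; d_h <- 2L
  # zero query/key projections: softmax of zeros is uniform, output is the
  # column mean of V replicated across rows
  Wv <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  out <- attention_head(diag(3), list(Wq = matrix(0, 3, 2),
                                      Wk = matrix(0, 3, 2), Wv = Wv))
  A <- attr(out, "attention")
  expect_equal(unname(A), matrix(1 / 3, 3, 3))
  expect_equal(unname(out[1, ]), colMeans(Wv))
  expect_equal(unname(out[2, ]), colMeans(Wv))
  # rows of the attention matrix always sum to 1
  set.seed(35)
  N <- matrix(runif(C * C), C, C)
  hp <- attention_head_params(C, d_h)
  A2 <- attr(attention_head(N, hp), "attention")
  expect_equal(rowSums(A2), rep(1, C), tolerance = 1e-6)
  # hand-set matrices against a direct matrix-algebra oracle
  Q <- N %*% hp$Wq; K <- N %*% hp$Wk; V <- N %*% hp$Wv
  S <- Q %*% t(K) / sqrt(d_h)
  E <- exp(S)
  want <- (E / rowSums(E)) %*% V
  expect_equal(unname(attention_head(N, hp)), unname(want), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(attention_head(N, list(Wq = matrix(0, 2, 2),
                                      Wk = matrix(0, 3, 2),
                                      Wv = matrix(0, 3, 2))), "head parameters")
})

test_that("subgraphs refine the residual seed and match a step-by-step oracle", {
  C <- 4L; h <- 2L; d_h <- 3L
  set.seed(36)
  N <- reweight(matrix(rbinom(16, 1, 0.5), 4, 4), 0.2)
  # all-zero parameters: the residual leaves the statistics graph untouched
  zero <- list(heads = replicate(h, list(Wq = matrix(0, C, d_h),
                                         Wk = matrix(0, C, d_h),
                                         Wv = matrix(0, C, d_h)),
                                 simplify = FALSE),
               Wo = matrix(0, h * d_h, C))
  expect_equal(build_subgraph(N, zero$heads, zero$Wo), N)
  # fixed-seed parameters: concat + project + residual + rectify, by hand
  pars <- with(list(), {
    set.seed(37)
    list(heads = lapply(1:h, function(i) attention_head_params(C, d_h)),
         Wo = matrix(rnorm(h * d_h * C, sd = 0.2), h * d_h, C))
  })
  got <- build_subgraph(N, pars$heads, pars$Wo)
  concat <- do.call(cbind, lapply(pars$heads, function(hp) {
    Q <- N %*% hp$Wq; K <- N %*% hp$Wk; V <- N %*% hp$Wv
    E <- exp(Q %*% t(K) / sqrt(d_h))
    (E / rowSums(E)) %*% V
  }))
  expect_equal(got, pmax(N + concat %*% pars$Wo, 0), tolerance = 1e-10)
  expect_true(all(got >= 0))
  expect_error(build_subgraph(N, pars$heads, matrix(0, h * d_h, C + 1)),
               "projection")
})

test_that("adjacency composition is an ordered rectified product", {
  expect_equal(compose_adjacency(list(diag(3), diag(3))), diag(3))
  set.seed(38)
  G1 <- matrix(runif(16), 4, 4)
  expect_equal(compose_adjacency(list(G1), normalize = FALSE), G1)
  Gs <- list(matrix(runif(16), 4, 4), matrix(runif(16), 4, 4),
             matrix(runif(16), 4, 4))
  expect_equal(compose_adjacency(Gs, normalize = FALSE),
               Gs[[1]] %*% Gs[[2]] %*% Gs[[3]])
  P <- compose_adjacency(Gs)
  expect_equal(rowSums(P), rep(1, 4))
  expect_error(compose_adjacency(list()), "at least one")
})

test_that("attention complexity estimate counts C^2 * d weights", {
  expect_equal(complexity_estimate(20, 64), 25600)
  expect_equal(complexity_estimate(60, 64), 230400)
  expect_equal(complexity_estimate(1, 1), 1)
  expect_error(complexity_estimate(0, 64), "positive")
  expect_error(complexity_estimate(20, -1), "positive")
})

test_that("the refined adjacency recovers planted block structure", {
  spec <- synth_spec(C = 8L, n = 500L, blocks = 2L, p_within = 0.6,
                     p_between = 0.05, seed = 11L)
  ann <- sample_labels(spec)
  g <- correlation_graph(ann, tau = 0.4, p = 0.2)
  P <- dame_forward(g$N, dame_params(8L, seed = 11L))
  off <- row(P) != col(P)
  wmask <- matrix(FALSE, 8, 8)
  for (b in spec$blocks) wmask[b, b] <- TRUE
  expect_gt(mean(P[off & wmask]), mean(P[off & !wmask]))
})
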