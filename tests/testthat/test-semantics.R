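test_that("label preprocessing tokenizes, strips stop words and stems", {
  v <- preprocess_labels(c("diabetic retinopathy", "normal",
                           "age-related macular degeneration"))
  expect_equal(v$tokens[[1]], c("diabet", "retinopathi"))
  expect_equal(v$tokens[[2]], "normal")
  # hyphen splits; 4 content words survive, each Porter-stemmed
  expect_equal(v$tokens[[3]], c("ag", "relat", "macular", "degener"))
  # a label made only of stop words falls back to its raw tokens
  v2 <- preprocess_labels("of the")
  expect_equal(v2$tokens[[1]], c("of", "the"))
  expect_error(preprocess_labels(c("x", "")), "empty")
  expect_error(preprocess_labels(character(0)), "no labels")
  expect_error(preprocess_labels(c("same", "same")), "duplicate")
})

test_that("Porter stemmer reproduces published reference stems", {
  cases <- c(caresses = "caress", ponies = "poni", cats = "cat",
             feed = "feed", agreed = "agre", plastered = "plaster",
             motoring = "motor", hopping = "hop", sized = "size",
             filing = "file", happy = "happi", relational = "relat",
             conditional = "condit", adjustable = "adjust",
             degeneration = "degener", myopia = "myopia")
  for (w in names(cases)) expect_equal(porter_stem(w), unname(cases[w]))
})

test_that("label embedding is the token-vector mean with seeded OOV fallback", {
  tab <- list(normal = c(1, 0, 0, 0), drusen = c(0, 1, 0, 0),
              myopia = c(0, 0, 1, 0))
  v <- preprocess_labels(c("normal", "drusen myopia"))
  H0 <- suppressWarnings(embed_labels(v, tab, dim = 4))
  expect_equal(unname(H0[1, ]), c(1, 0, 0, 0))       # exact lookup
  expect_equal(unname(H0[2, ]), c(0, 0.5, 0.5, 0))   # mean of two tokens
  # out-of-vocabulary token: warned about, deterministic and bitwise stable
  v3 <- preprocess_labels(c("normal", "xenolith"))
  expect_warning(H1 <- embed_labels(v3, tab, dim = 4, seed = 3),
                 "out-of-vocabulary")
  H2 <- suppressWarnings(embed_labels(v3, tab, dim = 4, seed = 3))
  expect_identical(H1, H2)
  expect_equal(sum(H1[2, ]^2), 1)                    # unit-norm fallback
  H3 <- suppressWarnings(embed_labels(v3, tab, dim = 4, seed = 4))
  expect_false(identical(H1[2, ], H3[2, ]))
  expect_error(embed_labels(v, list(a = 1:3, b = 1:4)), "inconsistent")
})

test_that("embedding files round-trip through the GloVe text format", {
  tab <- make_embeddings(c("alpha", "beta"), dim = 8, seed = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(tab, path)
  back <- read_embeddings(path, dim = 8)
  expect_equal(names(back), names(tab))
  expect_equal(back$alpha, tab$alpha, tolerance = 1e-6)
  expect_error(read_embeddings(path, dim = 300), "dimension")
})

test_that("cosine similarity is exact, symmetric and scale-invariant", {
  v <- c(1, 2, 3, rep(0, 7)); w <- c(3, 2, 1, rep(0, 7))
  expect_equal(cosine_similarity(v, v), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(v, w), sum(v * w) / sqrt(sum(v^2) * sum(w^2)))
  expect_equal(cosine_similarity(2.5 * v, 7 * w), cosine_similarity(v, w))
  expect_equal(cosine_similarity(v, w), cosine_similarity(w, v))
  expect_error(cosine_similarity(v, 0 * w), "zero")
})

test_that("gcn layer implements symmetric-normalised propagation", {
  # P = 0: self-loops only, identity weights, no activation -> identity map
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(H, matrix(0, 4, 4), diag(3), activate = FALSE), H)
  # C = 2 complete graph: D = diag(2, 2), every output row is the mean row
  H2 <- diag(2)
  out <- gcn_layer(H2, matrix(c(0, 1, 1, 0), 2, 2), diag(2), activate = FALSE)
  expect_equal(out, matrix(0.5, 2, 2))
  # shape contract
  expect_identical(dim(gcn_layer(matrix(0, 5, 7), diag(5) * 0.3,
                                 matrix(0, 7, 2))), c(5L, 2L))
  expect_error(gcn_layer(H, matrix(-0.1, 4, 4), diag(3)), "nonnegative")
  # symmetric P + I gives a symmetric propagation matrix
  set.seed(41)
  Ps <- matrix(runif(16), 4, 4); Ps <- (Ps + t(Ps)) / 2
  expect_true(isSymmetric(meddgtn:::.gcn_prop(Ps), tol = 1e-12))
})

test_that("two stacked layers produce the C x D classifier", {
  set.seed(42)
  C <- 4L; H0 <- matrix(rnorm(C * 6), C, 6)
  P <- matrix(runif(C * C), C, C)
  params <- list(W0 = matrix(rnorm(6 * 5), 6, 5),
                 W1 = matrix(rnorm(5 * 8), 5, 8))
  W <- gcn_forward(H0, P, params)
  # equals two sequential layer calls: leaky-ReLU then linear
  want <- gcn_layer(gcn_layer(H0, P, params$W0, activate = TRUE),
                    P, params$W1, activate = FALSE)
  expect_equal(unname(W), want)
  expect_identical(dim(W), c(4L, 8L))
  # identity-ish composition: P = 0, square identity weights
  params_id <- list(W0 = diag(6), W1 = diag(6))
  W2 <- gcn_forward(H0, matrix(0, C, C), params_id)
  expect_equal(unname(W2), ifelse(H0 > 0, H0, 0.2 * H0))
})
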