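test_that("fusion is the classifier-feature inner product", {
  x <- c(1, -2, 0.5)
  expect_equal(fuse(diag(3), x), x)
  expect_equal(fuse(matrix(0, 4, 3), x), rep(0, 4))
  W <- matrix(c(1, 0, 2,
                0, 1, 0,
                3, -1, 1,
                0, 0, 4), 3, 4)          # C = 3, D = 4 (column-major fill)
  xf <- c(1, 2, 0, -1)
  expect_equal(fuse(W, xf), as.numeric(W %*% xf))
  # batched form: one row of scores per image
  X <- cbind(xf, 2 * xf)
  expect_equal(fuse(W, X), t(W %*% X))
  expect_error(fuse(W, c(1, 2)), "dim")
})

test_that("BCE loss matches the sigmoid log-likelihood formula", {
  # sigmoid(0) = 0.5: per-label loss -log(0.5)
  expect_equal(bce_loss(0, 1), -log(0.5), tolerance = 1e-12)
  expect_equal(bce_loss(0, 0), -log(0.5), tolerance = 1e-12)
  # saturated-correct limit: loss -> 0
  expect_lt(bce_loss(30, 1), 1e-12)
  expect_lt(bce_loss(-30, 0), 1e-12)
  # random batch against a from-scratch evaluation of the formula
  set.seed(61)
  Z <- matrix(rnorm(24), 4, 6); Y <- matrix(rbinom(24, 1, 0.5), 4, 6)
  p <- 1 / (1 + exp(-Z))
  want <- -sum(Y * log(p) + (1 - Y) * log(1 - p)) / 4
  expect_equal(bce_loss(Z, Y), want, tolerance = 1e-6)
  expect_gte(bce_loss(Z, Y), 0)
  expect_error(bce_loss(Z, Y * 2), "binary")
})

test_that("training is deterministic under a fixed seed", {
  run_losses <- function() {
    fx <- tiny_model(seed = 62L)
    cfg <- train_config(lr_graph = 0.05, lr_cnn = 0.01, epochs = 2L,
                        batch_size = 4L, seed = 62L)
    train(fx$model, fx$dataset, cfg)$log$loss
  }
  l1 <- run_losses(); l2 <- run_losses()
  expect_identical(l1, l2)
  expect_length(l1, 2L)
})

test_that("one optimizer step moves parameters in both branches", {
  fx <- tiny_model(seed = 63L)
  before <- list(cnn = fx$model$backbone$params, gcn = fx$model$gcn,
                 dame = fx$model$dame)
  cfg <- train_config(lr_graph = 0.05, lr_cnn = 0.01, epochs = 1L,
                      batch_size = 6L, seed = 63L)
  train(fx$model, fx$dataset, cfg)
  delta <- function(a, b) meddgtn:::.param_norm(meddgtn:::.map2(a, b, `-`))
  expect_gt(delta(before$cnn, fx$model$backbone$params), 0)   # CNN branch
  expect_gt(delta(before$gcn, fx$model$gcn), 0)               # GCN weights
  expect_gt(delta(before$dame, fx$model$dame), 0)             # attention Wo
})

test_that("epochs = 0 returns the initialised model and an empty log", {
  fx <- tiny_model(seed = 64L)
  before <- fx$model$gcn
  out <- train(fx$model, fx$dataset, train_config(epochs = 0L))
  expect_identical(nrow(out$log), 0L)
  expect_identical(out$best_epoch, 0L)
  expect_identical(fx$model$gcn, before)
})

test_that("degenerate training inputs are rejected", {
  fx <- tiny_model(seed = 65L)
  expect_error(train(fx$model, list(images = NULL, y = fx$dataset$y)),
               "non-empty")
  expect_error(train(fx$model, list(images = fx$dataset$images,
                                    y = fx$dataset$y[1:2, ])),
               "disagree")
  expect_error(train_config(epochs = -1), "epochs")
  expect_error(train_config(lr_graph = 0), "positive")
})

test_that("the learning-rate schedule decays multiplicatively", {
  fx <- tiny_model(seed = 66L)
  cfg <- train_config(lr_graph = 0.04, lr_cnn = 0.008, epochs = 5L,
                      decay_every = 2L, decay_factor = 0.1,
                      batch_size = 6L, patience = 50L, seed = 66L)
  log <- train(fx$model, fx$dataset, cfg)$log
  expect_equal(log$lr_graph, 0.04 * c(1, 1, 0.1, 0.1, 0.01))
  expect_equal(log$lr_cnn, 0.008 * c(1, 1, 0.1, 0.1, 0.01))
})

test_that("checkpoints round-trip through save and load", {
  fx <- tiny_model(seed = 67L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fx$model, path, epoch = 3L)
  back <- load_checkpoint(path)
  expect_identical(back$labels, fx$model$labels)
  expect_equal(back$gcn, fx$model$gcn)
  expect_equal(back$N, fx$model$N)
  sc1 <- predict_scores(fx$model, fx$dataset$images[, , , 1:2, drop = FALSE])
  sc2 <- predict_scores(back, fx$dataset$images[, , , 1:2, drop = FALSE])
  expect_equal(sc1, sc2)
  # corrupt checkpoint: clear error naming the file
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})

test_that("model adjacency is row-stochastic and refreshed each forward", {
  fx <- tiny_model(seed = 68L)
  P <- model_adjacency(fx$model)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, fx$model$C), ignore_attr = TRUE)
  # perturbing the attention parameters changes the refined graph
  fx$model$dame[[1]]$Wo <- fx$model$dame[[1]]$Wo + 0.1
  expect_false(isTRUE(all.equal(P, model_adjacency(fx$model))))
})
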