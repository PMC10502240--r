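test_that("training loss combines clipped BCE with L1/L2 penalties", {
  P <- matrix(0.5, 3, 4); Y <- matrix(rbinom(12, 1, 0.5), 3, 4)
  expect_equal(bce_loss(P, Y), log(2), tolerance = 1e-12)

  exact <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(bce_loss(exact, exact), 1e-6)

  # unit-squared-norm weights with l2 = 1 add exactly 1 to the loss
  params <- list(fc = list(W = c(0.6, 0.8), b = 100))   # biases exempt
  expect_equal(training_loss(P, Y, params, l1_coef = 0, l2_coef = 1),
               log(2) + 1, tolerance = 1e-12)
  expect_equal(training_loss(P, Y, params, l1_coef = 1, l2_coef = 0),
               log(2) + 1.4, tolerance = 1e-12)
})

test_that("training is deterministic given a seed and stops with the patience rule", {
  set.seed(10)
  n <- 40
  X <- array(0, c(n, 60, 4))
  for (i in seq_len(n)) X[i, , ] <- t(one_hot(paste(
    sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")))
  Y <- matrix(rbinom(n * 2, 1, 0.4), n, 2)
  data <- list(X = X, bins = NULL, Y = Y)
  cfg <- seq_encoder_config("cnn", window_length = 60L, embed_dim = 8L,
                            kernels = c(4L, 4L, 4L), pools = c(2L, 2L),
                            dropout = c(0.2, 0.2, 0.2))
  build <- function() {
    set.seed(3)
    build_multimodal_model(cfg, NULL, n_events = 2L)
  }
  tc <- train_config(learning_rate = 1e-3, max_epochs = 4L, patience = 2L,
                     batch_size = 16L, seed = 5L)
  fit1 <- train_model(build(), data, data, tc)
  fit2 <- train_model(build(), data, data, tc)
  expect_identical(fit1$history, fit2$history)

  # with a zero learning rate validation never improves after epoch 1, so
  # training stops exactly patience epochs later and keeps epoch 1
  tc0 <- train_config(learning_rate = 0, max_epochs = 40L, patience = 4L,
                      batch_size = 16L, seed = 5L)
  fit0 <- train_model(build(), data, data, tc0)
  expect_equal(fit0$best_epoch, 1L)
  expect_equal(fit0$stopped_epoch, 5L)
  expect_equal(nrow(fit0$history), 5L)
})

test_that("the returned checkpoint is the best-validation epoch, never a later one", {
  set.seed(12)
  n <- 30
  X <- array(0, c(n, 60, 4))
  for (i in seq_len(n)) X[i, , ] <- t(one_hot(paste(
    sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")))
  Y <- matrix(rbinom(n * 2, 1, 0.5), n, 2)
  data <- list(X = X, bins = NULL, Y = Y)
  cfg <- seq_encoder_config("cnn", window_length = 60L, embed_dim = 8L,
                            kernels = c(4L, 4L, 4L), pools = c(2L, 2L),
                            dropout = c(0, 0, 0))
  set.seed(3)
  model <- build_multimodal_model(cfg, NULL, n_events = 2L)
  tc <- train_config(learning_rate = 5e-2, max_epochs = 8L, patience = 8L,
                     batch_size = 8L, seed = 5L)
  fit <- train_model(model, data, data, tc)
  final_loss <- training_loss(predict_profile(fit$model, data$X), data$Y,
                              fit$model$params, tc$l1_coef, tc$l2_coef)
  expect_equal(final_loss, min(fit$history$valid_loss), tolerance = 1e-9)
})

test_that("warm starting restores sequence-encoder parameters only", {
  set.seed(14)
  donor <- build_multimodal_model(mini_cnn_config(), NULL, n_events = 3L)
  dir <- withr::local_tempdir()
  save_checkpoint(donor, dir)

  g <- bin_grid(c(c1 = 1000), 200L)
  a <- matrix(1, 5, 5)
  nm <- normalize_contacts(interaction_matrix(g, Matrix::Matrix(a)), "row")
  set.seed(15)
  target <- build_multimodal_model(mini_cnn_config(), mini_struct_config(),
                                   n_events = 3L, normalized_matrix = nm)
  warmed <- load_checkpoint(dir, target, sequence_only = TRUE)
  expect_equal(warmed$params$seq, donor$params$seq)
  expect_false(isTRUE(all.equal(warmed$params$head, donor$params$head)))
})

test_that("training rejects label matrices that disagree with the model width", {
  set.seed(16)
  model <- build_multimodal_model(mini_cnn_config(), NULL, n_events = 3L)
  X <- array(0, c(4, 200, 4))
  bad <- list(X = X, bins = NULL, Y = matrix(0, 4, 5))
  expect_error(train_model(model, bad, bad, train_config()),
               "5 events but model emits 3")
})

test_that("AUROC matches explicit pair counting, with ties at one half", {
  expect_equal(auroc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_true(is.na(auroc(c(1, 2), c(1, 1))))
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    scores <- sample(1:8, n, replace = TRUE)   # many ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auroc(scores, labels), auroc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUPRC follows the average-precision convention", {
  # tie-free case: mean precision at each positive's rank
  set.seed(32)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.3)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  ap <- mean((cumsum(y) / seq_along(y))[y == 1])
  expect_equal(auprc(scores, labels), ap, tolerance = 1e-12)
  # perfect ranking gives 1, inverted ranking gives the minimum
  expect_equal(auprc(c(3, 2, 1), c(1, 1, 0)), 1.0)
  expect_true(is.na(auprc(1:3, c(0, 0, 0))))
})

test_that("random scores at a 2% positive rate give AUPRC near 0.02", {
  set.seed(33)
  labels <- rbinom(10000, 1, 0.02)
  scores <- runif(10000)
  expect_lt(abs(auprc(scores, labels) - 0.02), 0.01)
})

test_that("metrics reports exclude degenerate events from macro means", {
  probs <- cbind(c(0.9, 0.2, 0.8), c(0.5, 0.5, 0.5))
  labels <- cbind(c(1, 0, 1), c(0, 0, 0))
  rep <- metrics_report(probs, labels)
  expect_equal(rep$excluded_events, 2L)
  expect_equal(rep$macro_auroc, 1.0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(rep, path)
  expect_equal(nrow(utils::read.table(path, header = TRUE)), 2L)
})
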