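test_that("effect features vanish for identical windows and negate under swap", {
  set.seed(71)
  model <- build_multimodal_model(mini_cnn_config(), NULL, n_events = 6L)
  w <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  same <- effect_features(model, w, w)
  expect_equal(same$delta_prob, rep(0, 6))
  expect_equal(same$delta_logit, rep(0, 6))

  w2 <- w
  substr(w2, 100, 100) <- if (substr(w, 100, 100) == "A") "C" else "A"
  fwd <- effect_features(model, w, w2)
  rev <- effect_features(model, w2, w)
  expect_equal(fwd$delta_prob, -rev$delta_prob, tolerance = 1e-12)
  expect_equal(fwd$delta_logit, -rev$delta_logit, tolerance = 1e-12)

  masked <- effect_features(model, w, w2, event_mask = c(2L, 4L, 5L))
  expect_length(masked$delta_prob, 3L)
  expect_length(masked$delta_logit, 3L)
  expect_error(effect_features(model, w, substr(w, 1, 100)), "equal length")
})

test_that("zero-shot scores aggregate absolute probability differences", {
  expect_equal(zero_shot_score(c(0, 0, 0, 0)), 0)
  expect_equal(zero_shot_score(c(0.4, 0, 0, 0), "mean_abs"), 0.1)
  expect_equal(zero_shot_score(c(0.1, -0.3), "max_abs"), 0.3)
  expect_equal(zero_shot_score(c(0.3, -0.4), "l2"), 0.5)
  set.seed(72)
  for (i in 1:10) {
    d <- rnorm(8, sd = 0.2)
    for (m in c("mean_abs", "max_abs", "l2")) {
      s <- zero_shot_score(d, m)
      expect_gte(s, 0)
      expect_equal(s == 0, all(d == 0))
    }
  }
})

test_that("chromosome-grouped folds keep chromosomes intact and X with Y", {
  set.seed(73)
  chroms <- sample(c(paste0("chr", 1:22), "chrX", "chrY"), 600,
                   replace = TRUE)
  gf <- grouped_folds(chroms, n_folds = 5L, seed = 2L)
  expect_length(gf$fold, 600)
  expect_true(all(gf$fold %in% 1:5))
  # one fold per chromosome
  expect_true(all(tapply(gf$fold, chroms, function(f)
    length(unique(f))) == 1))
  expect_equal(unname(gf$group_fold["XY"]),
               unname(gf$fold[chroms == "chrX"][1]))
  expect_equal(unname(gf$group_fold["XY"]),
               unname(gf$fold[chroms == "chrY"][1]))
  # 23 groups into 5 folds: pigeonhole puts at least 3 groups everywhere
  per_fold <- table(gf$group_fold)
  expect_true(all(per_fold >= 3))
  # determinism
  gf2 <- grouped_folds(chroms, n_folds = 5L, seed = 2L)
  expect_identical(gf$fold, gf2$fold)
  expect_error(grouped_folds(c("chr1", "chr2"), n_folds = 5L), "groups")
})

test_that("eQTL cross-validation separates separable features and not shuffled labels", {
  set.seed(74)
  n <- 600
  chroms <- sample(paste0("chr", 1:10), n, replace = TRUE)
  labels <- rbinom(n, 1, 0.5)
  feats <- cbind(2 * labels - 1 + rnorm(n, sd = 0.1), rnorm(n))
  folds <- grouped_folds(chroms, n_folds = 5L, seed = 1L)
  res <- eqtl_crossval(feats, labels, folds)
  expect_equal(mean(res$auroc), 1.0, tolerance = 0.01)

  perm <- sample(labels)
  res0 <- eqtl_crossval(cbind(rnorm(n), rnorm(n), rnorm(n)), perm, folds)
  expect_gt(mean(res0$auroc), 0.40)
  expect_lt(mean(res0$auroc), 0.60)

  expect_error(
    eqtl_crossval(feats, labels, folds, log2fc = rnorm(n), cutoff = 99),
    "no variant passes")
})

test_that("a held-out tuning set drives the ridge-penalty choice", {
  set.seed(75)
  n <- 300
  labels <- rbinom(n, 1, 0.5)
  feats <- cbind(2 * labels - 1 + rnorm(n, sd = 0.5), rnorm(n))
  tune_labels <- rbinom(80, 1, 0.5)
  tune_feats <- cbind(2 * tune_labels - 1 + rnorm(80, sd = 0.5), rnorm(80))
  folds <- rep(1:3, length.out = n)
  res <- eqtl_crossval(feats, labels, folds, tune_features = tune_feats,
                       tune_labels = tune_labels)
  expect_equal(nrow(res), 3)
  expect_true(all(res$lambda > 0))
  expect_gt(mean(res$auroc), 0.8)
})

test_that("the Siamese classifier is exactly symmetric and defaults to zero-shot", {
  cfg <- variant_config(76)
  ds <- simulate_dataset(cfg)
  oracle <- oracle_sequence_model(cfg, ds$drivers)
  vw <- variant_windows_of(ds)
  te <- 1:40

  zs <- fit_siamese(oracle, list(y = integer(0)), NULL)
  expect_equal(zs$type, "zero_shot")
  z1 <- siamese_predict(zs, vw$ref[te], vw$alt[te], vw$bins[te])
  # the zero-shot path equals the mean absolute probability difference
  manual <- vapply(te, function(i)
    zero_shot_score(effect_features(oracle, vw$ref[i], vw$alt[i],
                                    vw$bins[i])), numeric(1))
  expect_equal(z1, manual, tolerance = 1e-12)

  pick <- function(ii) list(ref = vw$ref[ii], alt = vw$alt[ii],
                            bins = vw$bins[ii], y = vw$v$effect[ii])
  sc <- fit_siamese(oracle, pick(41:120), pick(121:150),
                    l2_weight = 1e-11,
                    config = train_config(learning_rate = 3e-3,
                                          max_epochs = 3L, patience = 3L,
                                          batch_size = 16L, seed = 1L))
  s_fwd <- siamese_predict(sc, vw$ref[te], vw$alt[te], vw$bins[te])
  s_rev <- siamese_predict(sc, vw$alt[te], vw$ref[te], vw$bins[te])
  expect_identical(s_fwd, s_rev)   # bit-identical under input swap
  expect_true(all(s_fwd > 0 & s_fwd < 1))
})
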