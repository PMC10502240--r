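test_that("sequence similarity is positional identity over comparable bases", {
  expect_equal(sequence_similarity("ACGT", "ACGT"), 1.0)
  expect_equal(sequence_similarity("AAAA", "AAAT"), 0.75)
  expect_equal(sequence_similarity("ANAA", "ATAA"), 1.0)   # 3 comparable
  expect_equal(sequence_similarity("NN", "NN"), 0)
  expect_error(sequence_similarity("AC", "ACG"), "equal length")
  # k-mer cosine strategy: identical sequences reach 1
  expect_equal(sequence_similarity("ACGTACGTAC", "ACGTACGTAC",
                                   metric = "kmer_cosine"), 1.0)
})

test_that("profile similarity is the Jaccard index on binary vectors", {
  expect_equal(profile_similarity(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_equal(profile_similarity(c(1, 0, 1), c(1, 1, 0)), 1 / 3)
  expect_equal(profile_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_error(profile_similarity(c(0, 0), c(0, 0)), "all-zero")
})

test_that("percentile partition classifies pairs by rank disparity", {
  same <- data.frame(seq_sim = rep(0.5, 6), prof_sim = rep(0.2, 6),
                     freq = 1)
  p <- percentile_partition(same, margin = 10)
  expect_length(p$consistent, 6)
  expect_length(p$over, 0)
  expect_length(p$under, 0)

  four <- data.frame(seq_sim = c(0.1, 0.2, 0.3, 0.4),
                     prof_sim = c(0.4, 0.3, 0.2, 0.1), freq = 1)
  p4 <- percentile_partition(four, margin = 10)
  expect_equal(p4$under, c(1L, 2L))
  expect_equal(p4$over, c(3L, 4L))

  # the degenerate bound puts everything in the consistent cell
  p100 <- percentile_partition(four, margin = 100)
  expect_length(p100$consistent, 4)
  expect_error(percentile_partition(four, margin = 0), "margin")
  expect_error(percentile_partition(four, margin = 101), "margin")
})

test_that("partition cells are disjoint and exhaustive", {
  set.seed(21)
  for (i in 1:10) {
    pairs <- data.frame(seq_sim = runif(30), prof_sim = runif(30),
                        freq = rpois(30, 2) + 1)
    p <- percentile_partition(pairs, margin = 15)
    all_idx <- sort(c(p$over, p$consistent, p$under))
    expect_equal(all_idx, 1:30)
  }
})

test_that("exact rank-sum p-values match the spec's worked cases", {
  expect_equal(rank_sum_one_sided(c(1, 2), c(3, 4), "greater"), 1.0)
  expect_equal(rank_sum_one_sided(c(1, 2), c(3, 4), "less"), 1 / 6)
  expect_equal(rank_sum_one_sided(5, c(1, 2, 3), "greater"), 1 / 4)
  # identical multisets cannot produce small one-sided p-values
  x <- c(2, 2, 5)
  expect_gte(rank_sum_one_sided(x, x, "greater"), 0.5)
  expect_gte(rank_sum_one_sided(x, x, "less"), 0.5)
  expect_error(rank_sum_one_sided(numeric(0), 1, "less"), "empty")
})

test_that("exact rank-sum agrees with a bitmask enumeration oracle up to n = 8", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    nx <- sample(seq_len(n - 1), 1)
    vals <- sample(1:4, n, replace = TRUE)   # heavy ties on purpose
    x <- vals[seq_len(nx)]; y <- vals[(nx + 1):n]
    for (alt in c("greater", "less")) {
      expect_equal(rank_sum_one_sided(x, y, alt),
                   ranksum_oracle(x, y, alt),
                   tolerance = 1e-12,
                   info = paste("n =", n, "alt =", alt))
    }
  }
})

test_that("tie-free exact p-values match wilcox.test", {
  set.seed(17)
  for (rep in 1:10) {
    x <- sample(1:100, 5); y <- sample(101:200, 6) - 100.5
    p_gt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value)
    expect_equal(rank_sum_one_sided(x, y, "greater"), p_gt,
                 tolerance = 1e-12)
  }
})

test_that("large samples use a tie-corrected normal approximation close to wilcox.test", {
  set.seed(9)
  x <- rpois(25, 4); y <- rpois(30, 5)
  ours <- rank_sum_one_sided(x, y, "less")
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", exact = FALSE,
                       correct = TRUE)$p.value)
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("inflating under-cell frequencies never increases the under p-value", {
  set.seed(41)
  for (rep in 1:10) {
    u <- runif(8, 1, 5); cns <- runif(10, 1, 5)
    p0 <- rank_sum_one_sided(u, cns, "greater")
    for (delta in c(0.5, 2, 10)) {
      expect_lte(rank_sum_one_sided(u + delta, cns, "greater"), p0 + 1e-12)
    }
  }
})

test_that("the disparity test rejects on planted structure and not on flat frequencies", {
  # beta = 1: labels are purely community-driven, the strongest planting
  ds <- simulate_dataset(disparity_config(101, beta = 1))
  rep_planted <- run_disparity_test(ds$window_seqs, ds$Y, ds$window_bins,
                                    ds$matrix, frac = 0.2, repeats = 3,
                                    margin = 10, seed = 7)
  expect_true(all(rep_planted$repeats$p_under < 0.05))

  # all-equal positive frequencies: no direction can be significant
  flat <- interaction_matrix(ds$grid,
                             Matrix::Matrix(1, ds$grid$total_bins,
                                            ds$grid$total_bins))
  rep_flat <- run_disparity_test(ds$window_seqs, ds$Y, ds$window_bins,
                                 flat, frac = 0.1, repeats = 2,
                                 margin = 10, seed = 7)
  expect_true(all(rep_flat$repeats$p_under >= 0.5, na.rm = TRUE))
  expect_true(all(rep_flat$repeats$p_over >= 0.5, na.rm = TRUE))

  expect_error(
    run_disparity_test(ds$window_seqs, ds$Y, ds$window_bins, ds$matrix,
                       frac = 1e-5, seed = 1),
    "increase frac")
})

test_that("report writing produces a parseable TSV", {
  ds <- simulate_dataset(disparity_config(102, beta = 0.5))
  rep <- run_disparity_test(ds$window_seqs, ds$Y, ds$window_bins,
                            ds$matrix, frac = 0.1, repeats = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_test_report(rep, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 2)
  expect_true(all(c("p_under", "p_over") %in% names(back)))
})

test_that("label-similarity Spearman is 1 for perfect predictions and ~0 for noise", {
  set.seed(4)
  Y <- matrix(rbinom(200 * 8, 1, 0.3), 200, 8)
  keep <- rowSums(Y) > 0
  Y <- Y[keep, , drop = FALSE]
  perfect <- label_similarity_spearman(Y, Y, n_pairs = 300, seed = 2)
  expect_equal(perfect$rho_all, 1.0)

  noise <- matrix(runif(nrow(Y) * 8), nrow(Y), 8)
  indep <- label_similarity_spearman(Y, noise, n_pairs = 1000, seed = 2,
                                     pred_metric = "cosine")
  expect_lt(abs(indep$rho_all), 0.1)

  expect_error(label_similarity_spearman(Y, Y, n_pairs = 2), "n_pairs")
})

test_that("per-cell Spearman breakdown reports all three disparity cells", {
  ds <- simulate_dataset(disparity_config(103, beta = 0.5))
  res <- label_similarity_spearman(ds$Y, ds$Y, n_pairs = 400, seed = 5,
                                   seqs = ds$window_seqs, margin = 10)
  expect_true(all(c("rho_over", "rho_consistent", "rho_under") %in%
                    names(res)))
  expect_equal(res$rho_consistent, 1.0)
})
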