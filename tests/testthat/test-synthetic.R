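test_that("fixtures regenerate byte-identically from (config, seed)", {
  cfg <- synthetic_config(n_chroms = 2L, chrom_length = 10000L,
                          n_variants = 20L, seed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("genome.fa", "bins.bed", "contacts.tsv", "labels.tsv",
              "variants.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("motif planting hits a binomial-consistent fraction of windows", {
  cfg <- synthetic_config(n_chroms = 4L, chrom_length = 60000L,
                          motifs = "TGACTCAG", n_events = 1L,
                          motif_fraction = 0.3, near_motif_fraction = 0,
                          n_variants = 0L, seed = 7L)
  g <- generate_genome(cfg)
  n <- nrow(g$bins)
  planted <- sum(g$plants$type == "motif")
  ci <- qbinom(c(0.005, 0.995), n, 0.3)
  expect_gte(planted, ci[1])
  expect_lte(planted, ci[2])

  # a zero planting fraction leaves a pure background genome
  cfg0 <- synthetic_config(n_chroms = 1L, chrom_length = 8000L,
                           motif_fraction = 0, near_motif_fraction = 0,
                           n_variants = 0L, seed = 7L)
  g0 <- generate_genome(cfg0)
  expect_equal(nrow(g0$plants), 0L)
})

test_that("contact maps follow the community block model with distance decay", {
  cfg <- synthetic_config(n_chroms = 2L, chrom_length = 40000L,
                          resolution = 2000L, n_communities = 4L,
                          community_assignment = "round_robin",
                          intra_rate = 10, inter_rate = 0, n_variants = 0L,
                          seed = 3L)
  grid <- bin_grid(stats::setNames(rep(cfg$chrom_length, 2),
                                   c("chr1", "chr2")), cfg$resolution)
  hic0 <- generate_hic(cfg, grid, expectation = TRUE)
  m <- as.matrix(hic0$matrix$values)
  same <- outer(hic0$communities, hic0$communities, "==")
  expect_true(all(m[!same] == 0))         # inter_rate 0, expectation mode
  expect_true(all(m[same] > 0))

  cfg2 <- synthetic_config(n_chroms = 2L, chrom_length = 40000L,
                           resolution = 2000L, intra_rate = 10,
                           inter_rate = 1, n_variants = 0L, seed = 4L)
  hic <- generate_hic(cfg2, grid)
  mm <- as.matrix(hic$matrix$values)
  expect_equal(mm, t(mm))
  same2 <- outer(hic$communities, hic$communities, "==")
  expect_gt(mean(mm[same2]), mean(mm[!same2]))
})

test_that("labels follow their drivers and flip with epsilon only", {
  cfg <- synthetic_config(n_chroms = 2L, chrom_length = 20000L,
                          beta = 0, epsilon = 0, n_variants = 0L, seed = 5L)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$drivers$driver == "sequence"))
  for (e in seq_len(cfg$n_events)) {
    expect_equal(ds$Y[, e],
                 as.integer(grepl(ds$drivers$motif[e], ds$bin_seqs,
                                  fixed = TRUE)))
  }

  cfg1 <- synthetic_config(n_chroms = 2L, chrom_length = 20000L,
                           resolution = 2000L, beta = 1, epsilon = 0,
                           n_variants = 0L, seed = 6L)
  ds1 <- simulate_dataset(cfg1)
  expect_true(all(ds1$drivers$driver == "structure"))
  # windows sharing a contact bin share every label
  for (b in unique(ds1$window_bins)) {
    rows <- ds1$Y[ds1$window_bins == b, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col)
      length(unique(col)) == 1)))
  }
})

test_that("sequence-driven positive rates track the planting fraction", {
  cfg <- synthetic_config(n_chroms = 4L, chrom_length = 40000L,
                          motifs = "CACGTGAC", n_events = 1L,
                          motif_fraction = 0.3, near_motif_fraction = 0,
                          beta = 0, epsilon = 0, n_variants = 0L, seed = 8L)
  ds <- simulate_dataset(cfg)
  n <- nrow(ds$Y)
  # chance occurrences add a little mass on top of the planted fraction
  ci <- qbinom(c(0.005, 0.995), n, 0.3) / n
  expect_gte(mean(ds$Y), ci[1])
  expect_lte(mean(ds$Y), ci[2] + 0.02)
})

test_that("variants change exactly what their labels claim", {
  cfg <- variant_config(9)
  ds <- simulate_dataset(cfg)
  v <- ds$variants
  expect_equal(sum(v$effect), nrow(v) / 2)     # 50/50 balance
  expect_true(all(v$eqtl_sign[v$effect == 1] %in% c(-1L, 1L)))
  expect_true(all(v$eqtl_sign[v$effect == 0] == 0L))

  edited_bin <- function(i) {
    w <- v$window[i]
    bs <- get_sequence(ds$assembly, ds$bins$chrom[w], ds$bins$start[w],
                       ds$bins$end[w])
    at <- v$pos[i] - ds$bins$start[w]
    substr(bs, at, at) <- v$alt[i]
    list(before = get_sequence(ds$assembly, ds$bins$chrom[w],
                               ds$bins$start[w], ds$bins$end[w]),
         after = bs)
  }
  for (i in seq_len(nrow(v))) {
    e <- v$event[i]
    b <- edited_bin(i)
    if (v$effect[i] == 1 && v$eqtl_sign[i] == -1) {
      motif <- cfg$motifs[e]
      expect_true(grepl(motif, b$before, fixed = TRUE))
      expect_false(grepl(motif, b$after, fixed = TRUE))
    } else if (v$effect[i] == 1 && v$eqtl_sign[i] == 1) {
      motif <- cfg$motifs[e]
      expect_false(grepl(motif, b$before, fixed = TRUE))
      expect_true(grepl(motif, b$after, fixed = TRUE))
    } else {
      for (m in unique(cfg$motifs)) {
        expect_equal(grepl(m, b$before, fixed = TRUE),
                     grepl(m, b$after, fixed = TRUE))
      }
    }
  }
  # effect variants sit on sequence-driven events only
  seq_ev <- ds$drivers$event[ds$drivers$driver == "sequence"]
  expect_true(all(v$event[v$effect == 1] %in% seq_ev))
})

test_that("strand doubling emits reverse-complement samples with shared labels", {
  cfg <- synthetic_config(n_chroms = 2L, chrom_length = 10000L,
                          n_variants = 0L, seed = 10L)
  ds <- simulate_dataset(cfg)
  s <- assemble_samples(ds)
  n <- length(ds$window_seqs)
  expect_equal(dim(s$X)[1], 2L * n)
  expect_equal(s$Y[1:n, ], s$Y[(n + 1):(2 * n), ])
  expect_equal(s$seqs[n + 1], reverse_complement(s$seqs[1]))
  expect_equal(s$strand, rep(c("+", "-"), each = n))

  single <- assemble_samples(ds, both_strands = FALSE)
  expect_equal(dim(single$X)[1], n)
})

test_that("the constructed reference model tracks motif presence per event", {
  cfg <- variant_config(11)
  ds <- simulate_dataset(cfg)
  oracle <- oracle_sequence_model(cfg, ds$drivers)
  probs <- predict_profile(oracle, onehot_windows(ds$window_seqs))
  occ_before <- function(seqs, pat, limit) {
    vapply(seqs, function(s) {
      hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
      any(hits > 0 & hits <= limit)
    }, logical(1), USE.NAMES = FALSE)
  }
  L <- cfg$window_length
  for (e in which(ds$drivers$driver == "sequence")) {
    m <- ds$drivers$motif[e]
    rc <- reverse_complement(m)
    # the detector is strand-symmetric; occurrences beginning in the last
    # dozen bases sit past the pooled receptive field and are left out
    detectable <- occ_before(ds$bin_seqs, m, L - 19) |
      occ_before(ds$bin_seqs, rc, L - 19)
    present <- grepl(m, ds$bin_seqs, fixed = TRUE) |
      grepl(rc, ds$bin_seqs, fixed = TRUE)
    expect_true(all(probs[detectable, e] > 0.5))
    expect_true(all(probs[!present, e] < 0.5))
  }
})
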