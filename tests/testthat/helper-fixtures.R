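# Shared fixture builders. All are deterministic functions of their seed.

toy_assembly <- function() {
  genome_assembly(c(c1 = "ACGTACGTACGTACGTACGT", c2 = "TTTTGGGGCCCCAAAA"))
}

# miniature sequence encoder configs used throughout the unit tests
mini_cnn_config <- function(window_length = 200L, embed_dim = 16L) {
  seq_encoder_config("cnn", window_length = window_length,
                     embed_dim = embed_dim, kernels = c(8L, 8L, 12L),
                     dropout = c(0, 0, 0))
}

mini_rnn_config <- function(window_length = 200L, embed_dim = 16L) {
  seq_encoder_config("cnn_rnn", window_length = window_length,
                     embed_dim = embed_dim, kernels = 8L, lstm_units = 6L,
                     dropout = 0)
}

mini_struct_config <- function(variant = "mlp") {
  struct_encoder_config(variant, node_feature_dim = 8L,
                        gcn_hidden = c(8L, 8L), struct_embed_dim = 8L,
                        mlp_hidden = c(16L, 16L))
}

# study conditions: structure-vs-sequence model comparison fixture
comparison_config <- function(seed) {
  synthetic_config(n_chroms = 4L, chrom_length = 15000L, bin_length = 100L,
                   window_length = 500L, resolution = 2500L, n_events = 8L,
                   community_assignment = "round_robin", beta = 0.5,
                   epsilon = 0.05, n_variants = 0L, seed = seed)
}

# study conditions: variant-effect (zero-/few-shot) fixture; window equals
# the bin so event labels are pure presence calls on the model input
variant_config <- function(seed) {
  synthetic_config(n_chroms = 4L, chrom_length = 30000L, bin_length = 200L,
                   window_length = 200L, resolution = 3000L, n_events = 8L,
                   motif_fraction = 0.3, near_motif_fraction = 0.25,
                   community_assignment = "round_robin", beta = 0.5,
                   epsilon = 0.02, n_variants = 700L, seed = seed)
}

# study conditions: disparity-test fixture
disparity_config <- function(seed, beta) {
  synthetic_config(n_chroms = 2L, chrom_length = 30000L, bin_length = 200L,
                   window_length = 1000L, resolution = 2000L, n_events = 8L,
                   community_assignment = "round_robin", beta = beta,
                   epsilon = 0.05, n_variants = 0L, seed = seed)
}

# reference/alternate windows plus contact bins for every dataset variant
variant_windows_of <- function(ds) {
  v <- ds$variants
  ref <- character(nrow(v)); alt <- character(nrow(v))
  bins <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    w <- apply_variant(ds$assembly, v[i, ], ds$config$window_length)
    ref[i] <- w$ref_window
    alt[i] <- w$alt_window
    bins[i] <- bin_of(ds$grid, v$chrom[i], v$pos[i] - 1L)
  }
  list(ref = ref, alt = alt, bins = bins, v = v)
}

# train multimodal and sequence-only miniatures on a comparison fixture and
# return their macro-AUPRC on the structure-driven events of the held-out
# chromosome
structure_gap_trial <- function(seed) {
  cfg <- comparison_config(seed)
  ds <- simulate_dataset(cfg)
  samples <- assemble_samples(ds)
  ch <- unique(samples$chrom)
  train <- samples_subset(samples, ch[1:2])
  valid <- samples_subset(samples, ch[3])
  test <- samples_subset(samples, ch[4])
  seq_cfg <- seq_encoder_config("cnn", window_length = 500L,
                                embed_dim = 64L, kernels = c(16L, 24L, 32L))
  struct_cfg <- struct_encoder_config("mlp", struct_embed_dim = 16L,
                                      mlp_hidden = c(32L, 32L))
  nm <- normalize_contacts(ds$matrix, "row")
  tc <- train_config(learning_rate = 2e-3, max_epochs = 10L, patience = 4L,
                     batch_size = 64L, seed = seed, l2_coef = 1e-6)
  set.seed(seed)
  mm <- build_multimodal_model(seq_cfg, struct_cfg, n_events = ncol(ds$Y),
                               normalized_matrix = nm)
  fit_mm <- train_model(mm, train, valid, tc)
  set.seed(seed)
  so <- build_multimodal_model(seq_cfg, NULL, n_events = ncol(ds$Y))
  fit_so <- train_model(so, train, valid, tc)
  sd_ev <- which(ds$drivers$driver == "structure")
  p_mm <- predict_profile(fit_mm$model, test$X, test$bins)
  p_so <- predict_profile(fit_so$model, test$X, test$bins)
  list(
    multimodal = metrics_report(p_mm[, sd_ev, drop = FALSE],
                                test$Y[, sd_ev, drop = FALSE])$macro_auprc,
    seq_only = metrics_report(p_so[, sd_ev, drop = FALSE],
                              test$Y[, sd_ev, drop = FALSE])$macro_auprc,
    n_structure_events = length(sd_ev))
}

# zero-shot and few-shot pathogenicity AUPRC on a variant fixture, using
# the constructed reference encoder as the warm start
fewshot_trial <- function(seed) {
  cfg <- variant_config(seed)
  ds <- simulate_dataset(cfg)
  oracle <- oracle_sequence_model(cfg, ds$drivers)
  vw <- variant_windows_of(ds)
  n <- length(vw$ref)
  set.seed(seed)
  idx <- sample.int(n)
  tr <- idx[1:400]; va <- idx[401:500]; te <- idx[501:n]
  pick <- function(ii) list(ref = vw$ref[ii], alt = vw$alt[ii],
                            bins = vw$bins[ii], y = vw$v$effect[ii])
  zs <- fit_siamese(oracle, list(y = integer(0)), NULL)
  z_scores <- siamese_predict(zs, vw$ref[te], vw$alt[te], vw$bins[te])
  sc <- fit_siamese(oracle, pick(tr), pick(va), l2_weight = 1e-11,
                    config = train_config(learning_rate = 3e-3,
                                          max_epochs = 30L, patience = 10L,
                                          batch_size = 16L, seed = seed))
  f_scores <- siamese_predict(sc, vw$ref[te], vw$alt[te], vw$bins[te])
  list(zero = auprc(z_scores, vw$v$effect[te]),
       few = auprc(f_scores, vw$v$effect[te]),
       classifier = sc, test_idx = te, vw = vw)
}

# independent oracle: one-sided rank-sum p-value by enumeration over all
# subsets chosen with a bitmask sweep (a different mechanism from the
# implementation's utils::combn route)
ranksum_oracle <- function(x, y, alternative) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y), ties.method = "average")
  w_obs <- sum(r[seq_len(nx)])
  ws <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[1:n])
    if (sum(bits) != nx) next
    ws <- c(ws, sum(r[bits == 1]))
  }
  if (alternative == "greater") mean(ws >= w_obs - 1e-9)
  else mean(ws <= w_obs + 1e-9)
}

# independent oracle: AUROC by explicit positive-negative pair counting
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# run the CLI dispatcher quietly, returning its exit code
capture_cli <- function(args) {
  code <- NULL
  suppressWarnings(suppressMessages(
    utils::capture.output(code <- ef_cli(args))))
  code
}
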