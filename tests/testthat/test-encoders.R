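random_onehot <- function(n, L, seed = 1) {
  set.seed(seed)
  X <- array(0, c(n, L, 4))
  for (i in seq_len(n))
    X[i, , ] <- t(one_hot(paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = "")))
  X
}

test_that("default encoder configs carry the published constants", {
  cnn <- seq_encoder_config("cnn")
  expect_equal(cnn$kernels, c(320L, 480L, 960L))
  expect_equal(cnn$kernel_size, 8L)
  expect_equal(cnn$pools, c(4L, 4L))
  expect_equal(cnn$embed_dim, 925L)
  expect_equal(cnn$window_length, 1000L)

  rnn <- seq_encoder_config("cnn_rnn")
  expect_equal(rnn$kernels, 320L)
  expect_equal(rnn$kernel_size, 26L)
  expect_equal(rnn$pools, 13L)
  expect_equal(rnn$lstm_units, 320L)
  expect_equal(rnn$embed_dim, 925L)

  st <- struct_encoder_config("gcn_topo")
  expect_equal(st$node_feature_dim, 768L)
  expect_equal(st$gcn_layers, 3L)
  expect_equal(st$struct_embed_dim, 128L)
})

test_that("miniature encoders embed to the configured dimension and reject bad shapes", {
  for (cfg in list(mini_cnn_config(), mini_rnn_config())) {
    set.seed(1)
    enc <- build_sequence_encoder(cfg)
    X <- random_onehot(3, 200)
    emb <- epifusion:::seq_encoder_fwd(enc, X)$out
    expect_equal(dim(emb), c(3L, 16L))
    expect_true(all(is.finite(emb)))
    # all-N windows still produce finite embeddings
    zero <- array(0, c(2, 200, 4))
    expect_true(all(is.finite(epifusion:::seq_encoder_fwd(enc, zero)$out)))
    expect_error(epifusion:::seq_encoder_fwd(enc, random_onehot(2, 150)),
                 "one-hot")
  }
})

test_that("topology-only GCN starts from all-ones node features", {
  g <- bin_grid(c(c1 = 1000), 200L)
  set.seed(2)
  a <- matrix(rpois(25, 2), 5, 5); a <- pmax(a, t(a))
  nm <- normalize_contacts(interaction_matrix(g, Matrix::Matrix(a)),
                           "sym_loop")
  enc <- build_structure_encoder(struct_encoder_config("gcn_topo"), nm)
  expect_true(all(enc$H0 == 1))
  expect_equal(ncol(enc$H0), 768L)
})

test_that("GCN embeddings are equivariant to node permutation", {
  g <- bin_grid(c(c1 = 1200), 200L)              # 6 bins
  set.seed(3)
  a <- matrix(rpois(36, 2), 6, 6); a <- pmax(a, t(a))
  perm <- sample(6)
  ap <- a[perm, perm]
  build <- function(mat, seed_val) {
    nm <- normalize_contacts(interaction_matrix(g, Matrix::Matrix(mat)),
                             "sym_loop")
    set.seed(seed_val)
    build_structure_encoder(mini_struct_config("gcn_topo"), nm)
  }
  e1 <- build(a, 42)
  e2 <- build(ap, 42)   # same weights, permuted topology
  out1 <- epifusion:::struct_encoder_fwd(e1, 0:5)$out
  out2 <- epifusion:::struct_encoder_fwd(e2, 0:5)$out
  expect_equal(out2, out1[perm, , drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("MLP structure encoder maps zero matrix rows to one shared embedding", {
  g <- bin_grid(c(c1 = 1000), 200L)
  vals <- Matrix::Matrix(0, 5, 5)
  vals[1, 2] <- vals[2, 1] <- 3
  nm <- normalize_contacts(interaction_matrix(g, vals), "row")
  set.seed(4)
  enc <- build_structure_encoder(mini_struct_config("mlp"), nm)
  out <- epifusion:::struct_encoder_fwd(enc, c(2L, 3L, 4L))$out
  expect_equal(out[1, ], out[2, ])  # both zero rows
  expect_equal(out[2, ], out[3, ])
  expect_error(epifusion:::struct_encoder_fwd(enc, 7L), "out of range")
})

test_that("the multimodal head concatenates and emits sigmoid probabilities", {
  g <- bin_grid(c(c1 = 1000), 200L)
  set.seed(5)
  a <- matrix(rpois(25, 2), 5, 5); a <- pmax(a, t(a))
  nm <- normalize_contacts(interaction_matrix(g, Matrix::Matrix(a)), "row")
  model <- build_multimodal_model(mini_cnn_config(), mini_struct_config(),
                                  n_events = 7L, normalized_matrix = nm)
  expect_equal(model$head_in, 16L + 8L)
  expect_equal(nrow(model$params$head$W), model$head_in)
  X <- random_onehot(3, 200)
  out <- model_forward(model, X, bins = c(0L, 1L, 4L))$probs
  expect_equal(dim(out), c(3L, 7L))
  expect_true(all(out > 0 & out < 1))

  # zeroed head weights collapse all outputs to sigmoid(bias)
  model$params$head$W[] <- 0
  model$params$head$b <- seq(-1, 2, length.out = 7)
  out0 <- model_forward(model, X, bins = c(0L, 1L, 4L))$probs
  for (i in 1:3)
    expect_equal(out0[i, ], 1 / (1 + exp(-model$params$head$b)),
                 tolerance = 1e-12)
})

test_that("sequence-only models ignore bins and evaluation mode is deterministic", {
  set.seed(6)
  model <- build_multimodal_model(mini_cnn_config(), NULL, n_events = 4L)
  X <- random_onehot(2, 200)
  p1 <- predict_profile(model, X)
  p2 <- predict_profile(model, X)
  expect_identical(p1, p2)
})

test_that("k-mer region embedders are deterministic and sequence-sensitive", {
  emb <- kmer_region_embedder(k = 4L, out_dim = 768L, seed = 9)
  s <- paste(rep("ACGT", 100), collapse = "")
  v1 <- embed_region(emb, s)
  v2 <- embed_region(emb, s)
  expect_identical(v1, v2)
  expect_length(v1, 768L)
  pa <- embed_region(emb, strrep("A", 400))
  pt <- embed_region(emb, strrep("T", 400))
  expect_gt(max(abs(pa - pt)), 0)
  expect_error(kmer_region_embedder(k = 9L), "k must be")
})

test_that("gcn_seq requires an embedder and consumes regional embeddings", {
  asm <- genome_assembly(c(c1 = paste(rep("ACGT", 500), collapse = "")))
  g <- bin_grid(asm, 500L)
  set.seed(7)
  a <- matrix(rpois(16, 2), 4, 4); a <- pmax(a, t(a))
  nm <- normalize_contacts(interaction_matrix(g, Matrix::Matrix(a)),
                           "sym_loop")
  expect_error(build_structure_encoder(mini_struct_config("gcn_seq"), nm),
               "gcn_seq requires")
  emb <- kmer_region_embedder(k = 3L, out_dim = 8L, seed = 1, subwindow = 250L)
  enc <- build_structure_encoder(mini_struct_config("gcn_seq"), nm,
                                 region_embedder = emb, assembly = asm,
                                 grid = g)
  expect_equal(dim(enc$H0), c(4L, 8L))
  expect_false(all(enc$H0 == 1))
  out <- epifusion:::struct_encoder_fwd(enc, 0:3)$out
  expect_equal(dim(out), c(4L, 8L))
})

test_that("checkpoints round-trip and fail loudly on manifest mismatch", {
  set.seed(8)
  model <- build_multimodal_model(mini_cnn_config(), NULL, n_events = 4L)
  X <- random_onehot(2, 200)
  p_before <- predict_profile(model, X)
  dir <- withr::local_tempdir()
  save_checkpoint(model, dir)

  set.seed(99)
  fresh <- build_multimodal_model(mini_cnn_config(), NULL, n_events = 4L)
  loaded <- load_checkpoint(dir, fresh)
  expect_equal(predict_profile(loaded, X), p_before, tolerance = 1e-12)

  other <- build_multimodal_model(mini_cnn_config(window_length = 300L),
                                  NULL, n_events = 4L)
  expect_error(load_checkpoint(dir, other), "manifest")
  expect_error(load_checkpoint(dir, other, sequence_only = TRUE),
               "sequence-encoder config")
})
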