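# Local sequence encoders, global structure encoders, and the multimodal
# concatenation head.

#' Sequence encoder configuration
#'
#' Two local-sequence encoder families are provided. The \code{cnn} variant
#' is three 1D convolution layers with two interspersed max-pooling layers;
#' the \code{cnn_rnn} variant is one convolution and one max-pooling layer
#' followed by a bidirectional LSTM. Defaults reproduce the published
#' constants of those baselines (320/480/960 kernels of size 8 with pools of
#' 4 for \code{cnn}; 320 kernels of size 26, pool 13, biLSTM width 320 per
#' direction for \code{cnn_rnn}; 925-dimensional embedding per kilobase);
#' every constant is overridable so miniature encoders can be used in tests.
#'
#' @param variant \code{"cnn"} or \code{"cnn_rnn"}.
#' @param window_length input window length in bases (default 1000).
#' @param embed_dim output embedding dimension (default 925).
#' @param kernels convolution kernel counts per layer.
#' @param kernel_size first-layer kernel width in bases (8 for \code{cnn},
#'   26 for \code{cnn_rnn}).
#' @param pools pooling widths.
#' @param lstm_units biLSTM hidden width per direction (\code{cnn_rnn}).
#' @param dropout dropout rates per stage (training only).
#' @return a \code{SequenceEncoderConfig} list.
#' @export
seq_encoder_config <- function(variant = c("cnn", "cnn_rnn"),
                               window_length = 1000L,
                               embed_dim = 925L,
                               kernels = NULL, kernel_size = NULL,
                               pools = NULL, lstm_units = NULL,
                               dropout = NULL) {
  variant <- match.arg(variant)
  if (variant == "cnn") {
    kernels <- kernels %||% c(320L, 480L, 960L)
    kernel_size <- kernel_size %||% 8L
    pools <- pools %||% c(4L, 4L)
    dropout <- dropout %||% c(0.2, 0.2, 0.5)
    if (length(kernels) != 3 || length(pools) != 2)
      stop("cnn variant needs 3 kernel counts and 2 pool widths")
  } else {
    kernels <- kernels %||% 320L
    kernel_size <- kernel_size %||% 26L
    pools <- pools %||% 13L
    lstm_units <- lstm_units %||% 320L
    dropout <- dropout %||% 0.2
  }
  structure(list(variant = variant, window_length = as.integer(window_length),
                 embed_dim = as.integer(embed_dim), kernels = kernels,
                 kernel_size = as.integer(kernel_size), pools = pools,
                 lstm_units = lstm_units, dropout = dropout),
            class = "SequenceEncoderConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flattened feature width entering the final affine layer
seq_encoder_flat_dim <- function(config) {
  L <- config$window_length
  k <- config$kernel_size
  if (config$variant == "cnn") {
    l1 <- (L - k + 1L) %/% config$pools[1]
    l2 <- (l1 - k + 1L) %/% config$pools[2]
    l3 <- l2 - k + 1L
    if (l3 < 1) stop("window too short for the cnn stack")
    l3 * config$kernels[3]
  } else {
    tl <- (L - k + 1L) %/% config$pools[1]
    if (tl < 1) stop("window too short for the cnn_rnn stack")
    tl * 2L * config$lstm_units
  }
}

#' Build a local sequence encoder
#'
#' Parameters are initialized from the current RNG state; seed before calling
#' for reproducibility. Optionally, the first convolution layer can be
#' seeded with known sequence motifs (informed kernel initialization, the
#' long-standing practice of initializing convolution kernels from known
#' binding-motif matrices): kernel \code{i} is set to the centered one-hot
#' pattern of \code{motif_init[i]} scaled by \code{motif_gain}, and the
#' remaining kernels stay random. Training then sharpens rather than
#' discovers the detectors, which matters at small sample sizes.
#'
#' @param config a \code{\link{seq_encoder_config}}.
#' @param motif_init optional character vector of k-mers (each at most
#'   \code{kernel_size} long; at most one per kernel).
#' @param motif_gain scale of the seeded kernels (default 1).
#' @return a \code{SequenceEncoder} with \code{$config} and \code{$params}.
#' @export
build_sequence_encoder <- function(config, motif_init = NULL,
                                   motif_gain = 1) {
  stopifnot(inherits(config, "SequenceEncoderConfig"))
  k <- config$kernel_size
  if (config$variant == "cnn") {
    params <- list(
      conv1 = conv1d_init(k, 4L, config$kernels[1]),
      conv2 = conv1d_init(k, config$kernels[1], config$kernels[2]),
      conv3 = conv1d_init(k, config$kernels[2], config$kernels[3]),
      fc = dense_init(seq_encoder_flat_dim(config), config$embed_dim))
  } else {
    params <- list(
      conv1 = conv1d_init(k, 4L, config$kernels[1]),
      bilstm = bilstm_init(config$kernels[1], config$lstm_units),
      fc = dense_init(seq_encoder_flat_dim(config), config$embed_dim))
  }
  if (!is.null(motif_init)) {
    if (length(motif_init) > config$kernels[1])
      stop("more seed motifs than first-layer kernels")
    if (any(nchar(motif_init) > k))
      stop("seed motif longer than kernel_size")
    for (i in seq_along(motif_init)) {
      oh <- one_hot(motif_init[i])        # 4 x len
      len <- ncol(oh)
      off <- (k - len) %/% 2L
      params$conv1$W[, , i] <- 0
      params$conv1$W[off + seq_len(len), , i] <-
        t(oh - 0.25) * motif_gain
    }
  }
  structure(list(config = config, params = params),
            class = "SequenceEncoder")
}

check_onehot_batch <- function(X, window_length) {
  d <- dim(X)
  if (length(d) != 3 || d[2] != window_length || d[3] != 4)
    stop(sprintf(
      "sequence input must be an (n, %d, 4) one-hot array, got (%s)",
      window_length, paste(d, collapse = ", ")))
}

seq_encoder_fwd <- function(enc, X, train = FALSE, params = enc$params) {
  cfg <- enc$config
  check_onehot_batch(X, cfg$window_length)
  n <- dim(X)[1]
  if (cfg$variant == "cnn") {
    c1 <- conv1d_fwd(X, params$conv1); r1 <- relu_fwd(c1$out)
    p1 <- maxpool1d_fwd(r1$out, cfg$pools[1])
    d1 <- dropout_fwd(p1$out, cfg$dropout[1], train)
    c2 <- conv1d_fwd(d1$out, params$conv2); r2 <- relu_fwd(c2$out)
    p2 <- maxpool1d_fwd(r2$out, cfg$pools[2])
    d2 <- dropout_fwd(p2$out, cfg$dropout[2], train)
    c3 <- conv1d_fwd(d2$out, params$conv3); r3 <- relu_fwd(c3$out)
    d3 <- dropout_fwd(r3$out, cfg$dropout[3], train)
    flat <- d3$out; dim(flat) <- c(n, length(flat) / n)
    fc <- dense_fwd(flat, params$fc); rf <- relu_fwd(fc$out)
    list(out = rf$out,
         cache = list(c1 = c1, r1 = r1, p1 = p1, d1 = d1, c2 = c2, r2 = r2,
                      p2 = p2, d2 = d2, c3 = c3, r3 = r3, d3 = d3,
                      flat_dim = dim(d3$out), fc = fc, rf = rf))
  } else {
    c1 <- conv1d_fwd(X, params$conv1); r1 <- relu_fwd(c1$out)
    p1 <- maxpool1d_fwd(r1$out, cfg$pools[1])
    d1 <- dropout_fwd(p1$out, cfg$dropout[1], train)
    bl <- bilstm_fwd(d1$out, params$bilstm)
    flat <- bl$out; dim(flat) <- c(n, length(flat) / n)
    fc <- dense_fwd(flat, params$fc); rf <- relu_fwd(fc$out)
    list(out = rf$out,
         cache = list(c1 = c1, r1 = r1, p1 = p1, d1 = d1, bl = bl,
                      flat_dim = dim(bl$out), fc = fc, rf = rf))
  }
}

seq_encoder_bwd <- function(enc, cache, dout, params = enc$params) {
  cfg <- enc$config
  dfc_in <- relu_bwd(dout, cache$rf$cache)
  fcb <- dense_bwd(dfc_in, cache$fc$cache, params$fc)
  dflat <- fcb$dX; dim(dflat) <- cache$flat_dim
  if (cfg$variant == "cnn") {
    dd3 <- dropout_bwd(dflat, cache$d3$cache)
    dr3 <- relu_bwd(dd3, cache$r3$cache)
    c3b <- conv1d_bwd(dr3, cache$c3$cache, params$conv3)
    dd2 <- dropout_bwd(c3b$dX, cache$d2$cache)
    dp2 <- maxpool1d_bwd(dd2, cache$p2$cache)
    dr2 <- relu_bwd(dp2, cache$r2$cache)
    c2b <- conv1d_bwd(dr2, cache$c2$cache, params$conv2)
    dd1 <- dropout_bwd(c2b$dX, cache$d1$cache)
    dp1 <- maxpool1d_bwd(dd1, cache$p1$cache)
    dr1 <- relu_bwd(dp1, cache$r1$cache)
    c1b <- conv1d_bwd(dr1, cache$c1$cache, params$conv1, need_dx = FALSE)
    list(grads = list(conv1 = c1b$grads, conv2 = c2b$grads,
                      conv3 = c3b$grads, fc = fcb$grads))
  } else {
    blb <- bilstm_bwd(dflat, cache$bl$cache, params$bilstm)
    dd1 <- dropout_bwd(blb$dX, cache$d1$cache)
    dp1 <- maxpool1d_bwd(dd1, cache$p1$cache)
    dr1 <- relu_bwd(dp1, cache$r1$cache)
    c1b <- conv1d_bwd(dr1, cache$c1$cache, params$conv1, need_dx = FALSE)
    list(grads = list(conv1 = c1b$grads, bilstm = blb$grads,
                      fc = fcb$grads))
  }
}

# ---- structure encoders -----------------------------------------------------

#' Structure encoder configuration
#'
#' Three global-structure encoder families: \code{mlp} featurizes each
#' sample by its bin's normalized interaction-matrix row and passes it
#' through two hidden layers; \code{gcn_topo} treats bins as graph nodes
#' with all-ones node features of \code{node_feature_dim} (default 768)
#' propagated through \code{gcn_layers} (default 3) graph convolutions;
#' \code{gcn_seq} replaces the all-ones features with regional sequence
#' embeddings from a pluggable embedder.
#'
#' @param variant \code{"mlp"}, \code{"gcn_topo"} or \code{"gcn_seq"}.
#' @param node_feature_dim GCN input node-feature width (default 768;
#'   ignored for \code{gcn_seq}, where the embedder decides).
#' @param gcn_layers number of graph convolutions (default 3).
#' @param gcn_hidden hidden widths for the first \code{gcn_layers - 1}
#'   convolutions (default 256, 256).
#' @param struct_embed_dim output embedding width (default 128).
#' @param mlp_hidden the MLP's two hidden widths (default 256, 256).
#' @return a \code{StructureEncoderConfig} list.
#' @export
struct_encoder_config <- function(variant = c("mlp", "gcn_topo", "gcn_seq"),
                                  node_feature_dim = 768L,
                                  gcn_layers = 3L,
                                  gcn_hidden = c(256L, 256L),
                                  struct_embed_dim = 128L,
                                  mlp_hidden = c(256L, 256L)) {
  variant <- match.arg(variant)
  if (gcn_layers != length(gcn_hidden) + 1L)
    stop("gcn_hidden must have gcn_layers - 1 widths")
  structure(list(variant = variant,
                 node_feature_dim = as.integer(node_feature_dim),
                 gcn_layers = as.integer(gcn_layers),
                 gcn_hidden = as.integer(gcn_hidden),
                 struct_embed_dim = as.integer(struct_embed_dim),
                 mlp_hidden = as.integer(mlp_hidden)),
            class = "StructureEncoderConfig")
}

#' Build a global structure encoder
#'
#' @param config a \code{\link{struct_encoder_config}}.
#' @param normalized_matrix a \code{NormalizedMatrix}: scheme \code{"row"}
#'   for \code{mlp}, \code{"sym_loop"} for the GCN variants.
#' @param region_embedder a \code{\link{kmer_region_embedder}} (or
#'   compatible), required for \code{gcn_seq}.
#' @param assembly the \code{GenomeAssembly}, required for \code{gcn_seq} to
#'   embed each bin's DNA.
#' @param grid the \code{BinGrid}, required for \code{gcn_seq}.
#' @return a \code{StructureEncoder} with \code{$config}, \code{$params} and
#'   fixed propagation inputs.
#' @export
build_structure_encoder <- function(config, normalized_matrix,
                                    region_embedder = NULL,
                                    assembly = NULL, grid = NULL) {
  stopifnot(inherits(config, "StructureEncoderConfig"))
  v <- normalized_matrix$values
  n_bins <- nrow(v)
  if (config$variant == "mlp") {
    if (normalized_matrix$scheme != "row")
      stop("mlp structure encoder expects row-normalized matrix")
    h <- config$mlp_hidden
    params <- list(fc1 = dense_init(n_bins, h[1]),
                   fc2 = dense_init(h[1], h[2]),
                   fc3 = dense_init(h[2], config$struct_embed_dim))
    return(structure(list(config = config, params = params, rows = v,
                          n_bins = n_bins), class = "StructureEncoder"))
  }
  if (normalized_matrix$scheme != "sym_loop")
    stop("GCN structure encoders expect sym_loop-normalized adjacency")
  if (config$variant == "gcn_topo") {
    H0 <- matrix(1, n_bins, config$node_feature_dim)
  } else {
    if (is.null(region_embedder) || is.null(assembly) || is.null(grid))
      stop("gcn_seq requires region_embedder, assembly and grid")
    H0 <- embed_all_bins(region_embedder, assembly, grid)
    config$node_feature_dim <- ncol(H0)
  }
  widths <- c(config$node_feature_dim, config$gcn_hidden,
              config$struct_embed_dim)
  params <- lapply(seq_len(config$gcn_layers), function(l)
    dense_init(widths[l], widths[l + 1]))
  names(params) <- paste0("gc", seq_len(config$gcn_layers))
  structure(list(config = config, params = params, A = v, H0 = H0,
                 n_bins = n_bins), class = "StructureEncoder")
}

# bins are 0-based global bin indices, one per sample
struct_encoder_fwd <- function(enc, bins, params = enc$params) {
  if (any(bins < 0) || any(bins >= enc$n_bins))
    stop("bin index out of range [0, ", enc$n_bins, ")")
  if (enc$config$variant == "mlp") {
    X <- as.matrix(enc$rows[bins + 1L, , drop = FALSE])
    f1 <- dense_fwd(X, params$fc1); r1 <- relu_fwd(f1$out)
    f2 <- dense_fwd(r1$out, params$fc2); r2 <- relu_fwd(f2$out)
    f3 <- dense_fwd(r2$out, params$fc3)
    return(list(out = f3$out,
                cache = list(f1 = f1, r1 = r1, f2 = f2, r2 = r2, f3 = f3)))
  }
  H <- enc$H0
  layers <- vector("list", enc$config$gcn_layers)
  for (l in seq_len(enc$config$gcn_layers)) {
    M <- as.matrix(enc$A %*% H)
    z <- dense_fwd(M, params[[l]])
    r <- relu_fwd(z$out)
    layers[[l]] <- list(M = M, z = z, r = r)
    H <- r$out
  }
  list(out = H[bins + 1L, , drop = FALSE],
       cache = list(layers = layers, bins = bins))
}

struct_encoder_bwd <- function(enc, cache, dout, params = enc$params) {
  if (enc$config$variant == "mlp") {
    f3b <- dense_bwd(dout, cache$f3$cache, params$fc3)
    dr2 <- relu_bwd(f3b$dX, cache$r2$cache)
    f2b <- dense_bwd(dr2, cache$f2$cache, params$fc2)
    dr1 <- relu_bwd(f2b$dX, cache$r1$cache)
    f1b <- dense_bwd(dr1, cache$f1$cache, params$fc1)
    return(list(grads = list(fc1 = f1b$grads, fc2 = f2b$grads,
                             fc3 = f3b$grads)))
  }
  # scatter per-sample gradients back onto graph nodes (duplicates summed)
  dH <- matrix(0, enc$n_bins, ncol(dout))
  agg <- rowsum(dout, group = cache$bins)
  dH[as.integer(rownames(agg)) + 1L, ] <- agg
  grads <- vector("list", enc$config$gcn_layers)
  for (l in rev(seq_len(enc$config$gcn_layers))) {
    st <- cache$layers[[l]]
    dz <- relu_bwd(dH, st$r$cache)
    zb <- dense_bwd(dz, st$z$cache, params[[l]])
    grads[[l]] <- zb$grads
    if (l > 1) dH <- as.matrix(enc$A %*% zb$dX)  # A symmetric
  }
  names(grads) <- paste0("gc", seq_len(enc$config$gcn_layers))
  list(grads = grads)
}

# ---- regional sequence embedder ---------------------------------------------

#' Deterministic k-mer regional sequence embedder
#'
#' A desk-scale regional embedder with the same contract as a pretrained
#' DNA language model: each bin's DNA is cut into 1-kb sub-windows, each
#' sub-window is described by its k-mer count vector, the sub-window vectors
#' are mean-pooled, and the pooled vector is projected to \code{out_dim} by
#' a fixed random matrix drawn once from \code{seed}. Output is
#' deterministic given (sequence, seed).
#'
#' @param k k-mer size (1..8).
#' @param out_dim output embedding width (default 768).
#' @param seed seed for the fixed projection.
#' @param subwindow sub-window size in bases (default 1000).
#' @return a \code{RegionEmbedder}.
#' @export
kmer_region_embedder <- function(k = 4L, out_dim = 768L, seed = 0L,
                                 subwindow = 1000L) {
  if (k < 1 || k > 8) stop("k must be in 1..8")
  nk <- 4L^k
  proj <- with_seed(seed, matrix(stats::rnorm(nk * out_dim, sd = 1 / sqrt(nk)),
                                 nk, out_dim))
  structure(list(k = as.integer(k), out_dim = as.integer(out_dim),
                 seed = as.integer(seed), subwindow = as.integer(subwindow),
                 proj = proj),
            class = "RegionEmbedder")
}

#' Embed one region's DNA
#'
#' @param embedder a \code{RegionEmbedder}.
#' @param sequence the region's DNA string.
#' @return numeric vector of length \code{out_dim}.
#' @export
embed_region <- function(embedder, sequence) {
  L <- nchar(sequence)
  starts <- seq(1L, L, by = embedder$subwindow)
  counts <- vapply(starts, function(s) {
    sub <- substr(sequence, s, min(s + embedder$subwindow - 1L, L))
    if (nchar(sub) < embedder$k) return(numeric(4^embedder$k))
    as.numeric(kmer_counts(sub, embedder$k))
  }, numeric(4^embedder$k))
  pooled <- rowMeans(matrix(counts, nrow = 4^embedder$k))
  as.numeric(pooled %*% embedder$proj)
}

embed_all_bins <- function(embedder, assembly, grid) {
  H <- matrix(0, grid$total_bins, embedder$out_dim)
  for (ci in seq_along(grid$chrom_names)) {
    chrom <- grid$chrom_names[ci]
    clen <- grid$chrom_lengths[[chrom]]
    for (b in seq_len(grid$n_bins[ci])) {
      s0 <- (b - 1L) * grid$resolution
      e0 <- min(s0 + grid$resolution, clen)
      seqs <- get_sequence(assembly, chrom, s0, e0)
      H[grid$offsets[ci] + b, ] <- embed_region(embedder, seqs)
    }
  }
  H
}

# run expr under a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- multimodal model -------------------------------------------------------

#' Build a multimodal epigenetic profile predictor
#'
#' Concatenates the local sequence embedding with (optionally) the global
#' structure embedding and (optionally) a scalar chromatin-accessibility
#' channel, and maps the concatenation through a fully connected layer with
#' \code{n_events} sigmoid outputs. With \code{struct_config = NULL} the
#' model is the sequence-only ablation.
#'
#' @param seq_config a \code{\link{seq_encoder_config}}.
#' @param struct_config a \code{\link{struct_encoder_config}} or \code{NULL}.
#' @param n_events number of predicted epigenetic events (default 919).
#' @param normalized_matrix \code{NormalizedMatrix} for the structure
#'   encoder (required unless \code{struct_config} is NULL).
#' @param region_embedder,assembly,grid passed through for \code{gcn_seq}.
#' @param accessibility optional per-bin accessibility vector enabling the
#'   1D accessibility channel (log1p-standardized, affine-embedded and
#'   appended to the concatenation).
#' @param acc_embed_dim width of the accessibility embedding (default 8).
#' @param seq_motif_init,seq_motif_gain optional informed initialization of
#'   first-layer sequence kernels, see \code{\link{build_sequence_encoder}}.
#' @return a \code{MultimodalModel}.
#' @export
build_multimodal_model <- function(seq_config, struct_config = NULL,
                                   n_events = 919L,
                                   normalized_matrix = NULL,
                                   region_embedder = NULL, assembly = NULL,
                                   grid = NULL, accessibility = NULL,
                                   acc_embed_dim = 8L,
                                   seq_motif_init = NULL,
                                   seq_motif_gain = 1) {
  seq_enc <- build_sequence_encoder(seq_config, seq_motif_init,
                                    seq_motif_gain)
  struct_enc <- NULL
  head_in <- seq_config$embed_dim
  if (!is.null(struct_config)) {
    if (is.null(normalized_matrix))
      stop("structure encoder requires a normalized matrix")
    struct_enc <- build_structure_encoder(struct_config, normalized_matrix,
                                          region_embedder, assembly, grid)
    head_in <- head_in + struct_config$struct_embed_dim
  }
  acc <- NULL
  if (!is.null(accessibility)) {
    a <- log1p(accessibility)
    acc <- list(values = (a - mean(a)) / max(stats::sd(a), 1e-12),
                dim = as.integer(acc_embed_dim))
    head_in <- head_in + acc_embed_dim
  }
  params <- list(seq = seq_enc$params, head = dense_init(head_in, n_events))
  if (!is.null(struct_enc)) params$struct <- struct_enc$params
  if (!is.null(acc)) params$acc <- dense_init(1L, acc$dim)
  stopifnot(nrow(params$head$W) == head_in)
  structure(list(seq_enc = seq_enc, struct_enc = struct_enc, acc = acc,
                 n_events = as.integer(n_events), head_in = head_in,
                 params = params),
            class = "MultimodalModel")
}

#' @exportS3Method print MultimodalModel
print.MultimodalModel <- function(x, ...) {
  cat(sprintf(
    "MultimodalModel: %s sequence encoder (%d-dim)%s -> %d sigmoid outputs\n",
    x$seq_enc$config$variant, x$seq_enc$config$embed_dim,
    if (!is.null(x$struct_enc))
      sprintf(" + %s structure encoder (%d-dim)", x$struct_enc$config$variant,
              x$struct_enc$config$struct_embed_dim) else " (sequence only)",
    x$n_events))
  invisible(x)
}

#' Forward pass of the multimodal model
#'
#' @param model a \code{MultimodalModel}.
#' @param X one-hot batch array (n, window_length, 4).
#' @param bins 0-based global bin index per sample (required when the model
#'   has a structure encoder or accessibility channel).
#' @param train logical; enables dropout.
#' @param params optional parameter tree overriding \code{model$params}.
#' @return list with \code{probs} (n x n_events, strictly inside (0,1)) and
#'   \code{cache} for the backward pass.
#' @export
model_forward <- function(model, X, bins = NULL, train = FALSE,
                          params = model$params) {
  sq <- seq_encoder_fwd(model$seq_enc, X, train, params$seq)
  parts <- list(sq$out)
  st <- NULL
  if (!is.null(model$struct_enc)) {
    if (is.null(bins)) stop("bins required for the structure encoder")
    st <- struct_encoder_fwd(model$struct_enc, bins, params$struct)
    parts <- c(parts, list(st$out))
  }
  ac <- NULL
  if (!is.null(model$acc)) {
    if (is.null(bins)) stop("bins required for the accessibility channel")
    aX <- matrix(model$acc$values[bins + 1L], ncol = 1)
    ac <- dense_fwd(aX, params$acc)
    acr <- relu_fwd(ac$out)
    parts <- c(parts, list(acr$out))
    ac$relu <- acr
  }
  concat <- do.call(cbind, parts)
  hd <- dense_fwd(concat, params$head)
  probs <- sigmoid(hd$out)
  list(probs = probs,
       cache = list(sq = sq, st = st, ac = ac, hd = hd,
                    widths = vapply(parts, ncol, integer(1))))
}

# dlogits: gradient of the loss w.r.t. the pre-sigmoid head outputs
model_backward <- function(model, cache, dlogits, params = model$params) {
  hb <- dense_bwd(dlogits, cache$hd$cache, params$head)
  w <- cache$widths
  off <- cumsum(c(0, w))
  dseq <- hb$dX[, (off[1] + 1):off[2], drop = FALSE]
  grads <- list(seq = seq_encoder_bwd(model$seq_enc, cache$sq$cache, dseq,
                                      params$seq)$grads,
                head = hb$grads)
  part <- 2L
  if (!is.null(model$struct_enc)) {
    dst <- hb$dX[, (off[part] + 1):off[part + 1], drop = FALSE]
    grads$struct <- struct_encoder_bwd(model$struct_enc, cache$st$cache,
                                       dst, params$struct)$grads
    part <- part + 1L
  }
  if (!is.null(model$acc)) {
    dac <- hb$dX[, (off[part] + 1):off[part + 1], drop = FALSE]
    dac <- relu_bwd(dac, cache$ac$relu$cache)
    grads$acc <- dense_bwd(dac, cache$ac$cache, params$acc)$grads
  }
  grads
}

#' Predict event probabilities for a batch of windows
#'
#' Evaluation-mode (deterministic, no dropout) forward pass, batched to
#' bound memory.
#'
#' @param model a \code{MultimodalModel}.
#' @param X one-hot batch array (n, window_length, 4).
#' @param bins 0-based bin indices per sample.
#' @param batch_size samples per forward batch.
#' @return an (n x n_events) probability matrix.
#' @export
predict_profile <- function(model, X, bins = NULL, batch_size = 256L) {
  n <- dim(X)[1]
  out <- matrix(0, n, model$n_events)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    out[s:e, ] <- model_forward(model, X[s:e, , , drop = FALSE],
                                if (!is.null(bins)) bins[s:e],
                                train = FALSE)$probs
  }
  out
}

# ---- checkpoints -------------------------------------------------------------

model_manifest <- function(model) {
  list(package = "epifusion",
       format_version = 1L,
       n_events = model$n_events,
       head_in = model$head_in,
       seq_config = unclass(model$seq_enc$config),
       struct_config = if (!is.null(model$struct_enc))
         unclass(model$struct_enc$config),
       has_accessibility = !is.null(model$acc))
}

#' Save a model checkpoint
#'
#' Writes a directory holding a JSON config manifest plus the parameter
#' arrays. Loading verifies the manifest and fails loudly on mismatch.
#'
#' @param model a \code{MultimodalModel}.
#' @param dir checkpoint directory (created).
#' @return \code{dir}, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(model_manifest(model),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(model$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' Load checkpoint parameters into a compatible model
#'
#' @param dir checkpoint directory.
#' @param model a freshly built \code{MultimodalModel} whose architecture
#'   must match the checkpoint manifest.
#' @param sequence_only if \code{TRUE}, only the sequence-encoder parameters
#'   are loaded (warm start); the manifests' sequence configs must agree but
#'   the rest of the architecture may differ.
#' @return the model with parameters replaced.
#' @export
load_checkpoint <- function(dir, model, sequence_only = FALSE) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in checkpoint ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  here <- model_manifest(model)
  if (sequence_only) {
    if (!identical_config(manifest$seq_config, here$seq_config))
      stop("checkpoint sequence-encoder config does not match the model ",
           "(window_length/variant/widths differ)")
    params <- readRDS(file.path(dir, "params.rds"))
    model$params$seq <- params$seq
    return(model)
  }
  if (!identical_config(manifest, here))
    stop("checkpoint manifest does not match the model architecture")
  model$params <- readRDS(file.path(dir, "params.rds"))
  model
}

# JSON round-trips drop types/attributes; compare field-by-field on values
identical_config <- function(a, b) {
  norm <- function(x) {
    if (is.list(x)) return(lapply(x, norm))
    if (is.null(x)) return(NULL)
    as.vector(unlist(x))
  }
  isTRUE(all.equal(norm(a), norm(b), tolerance = 1e-9,
                   check.attributes = FALSE))
}
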