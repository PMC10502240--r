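# Variant effect scoring: epigenetic-difference featurization, zero-shot
# scores, chromosome-grouped eQTL cross-validation, and the Siamese few-shot
# pathogenicity classifier.

#' Epigenetic-difference features for a variant
#'
#' Runs the model on the reference and alternate windows and returns the
#' per-event differences in predicted probability and in predicted log odds
#' (probabilities clipped before the logit).
#'
#' @param model a \code{MultimodalModel}.
#' @param ref_window,alt_window equal-length window sequences (strings).
#' @param bin_index 0-based global bin of the variant's window.
#' @param event_mask optional integer vector restricting features to
#'   cell-line-matched events.
#' @param clip probability clipping bound for the logit (default 1e-6).
#' @return an \code{EffectFeatures} list with \code{delta_prob} and
#'   \code{delta_logit}.
#' @export
effect_features <- function(model, ref_window, alt_window, bin_index = NULL,
                            event_mask = NULL, clip = 1e-6) {
  if (nchar(ref_window) != nchar(alt_window))
    stop("ref and alt windows must have equal length")
  X <- onehot_windows(c(ref_window, alt_window))
  bins <- if (!is.null(bin_index)) rep(bin_index, 2)
  p <- predict_profile(model, X, bins)
  p_ref <- p[1, ]; p_alt <- p[2, ]
  if (!is.null(event_mask)) {
    p_ref <- p_ref[event_mask]; p_alt <- p_alt[event_mask]
  }
  pc <- function(x) pmin(pmax(x, clip), 1 - clip)
  structure(list(delta_prob = p_alt - p_ref,
                 delta_logit = stats::qlogis(pc(p_alt)) -
                   stats::qlogis(pc(p_ref))),
            class = "EffectFeatures")
}

#' Zero-shot variant effect score
#'
#' Aggregates the absolute per-event probability differences into a scalar
#' pathogenicity indicator.
#'
#' @param features an \code{EffectFeatures} or a numeric delta-probability
#'   vector.
#' @param mode \code{"mean_abs"} (default), \code{"max_abs"} or \code{"l2"}.
#' @return nonnegative scalar; zero iff the probability differences are all
#'   zero.
#' @export
zero_shot_score <- function(features, mode = c("mean_abs", "max_abs", "l2")) {
  mode <- match.arg(mode)
  d <- if (inherits(features, "EffectFeatures")) features$delta_prob
       else features
  switch(mode,
         mean_abs = mean(abs(d)),
         max_abs = max(abs(d)),
         l2 = sqrt(sum(d^2)))
}

#' Chromosome-grouped cross-validation folds
#'
#' Assigns whole chromosomes to folds so no chromosome spans two folds; the
#' sex chromosomes X and Y always share a fold. Chromosome groups are placed
#' greedily (largest variant count first, into the currently lightest fold)
#' after a seeded shuffle that makes tie-breaking deterministic.
#'
#' @param chromosomes chromosome name per variant.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return a \code{GroupedFolds} list: \code{fold} (1-based fold id per
#'   variant), \code{group_fold} (named fold id per chromosome group),
#'   \code{n_folds}.
#' @export
grouped_folds <- function(chromosomes, n_folds = 5L, seed = 0L) {
  grp <- ifelse(sub("^chr", "", chromosomes) %in% c("X", "Y"), "XY",
                chromosomes)
  counts <- table(grp)
  if (length(counts) < n_folds)
    stop(sprintf("only %d chromosome groups for %d folds", length(counts),
                 n_folds))
  nms <- names(counts)
  ord <- with_seed(seed, sample.int(length(nms)))
  nms <- nms[ord][order(-as.integer(counts)[ord])]
  load <- numeric(n_folds)
  gf <- stats::setNames(integer(length(nms)), nms)
  for (g in nms) {
    f <- which.min(load)
    gf[g] <- f
    load[f] <- load[f] + counts[[g]]
  }
  structure(list(fold = unname(gf[grp]), group_fold = gf,
                 n_folds = as.integer(n_folds)),
            class = "GroupedFolds")
}

#' Chromosome-grouped eQTL cross-validation
#'
#' Fits an L2-regularized logistic regression (ridge) on the
#' delta-log-odds features for each fold's complement and evaluates on the
#' fold. The inverse-regularization strength is chosen on a held-out tuning
#' set when one is supplied (mirroring tuning on reserved chromosomes),
#' otherwise by internal cross-validation on the training folds.
#'
#' @param features numeric matrix (variants x events) of delta-log-odds.
#' @param labels binary outcome (1 = expression increase).
#' @param folds a \code{\link{grouped_folds}} result (or integer fold ids).
#' @param lambda_grid ridge penalty grid.
#' @param tune_features,tune_labels optional held-out tuning data.
#' @param log2fc optional per-variant log2 fold change enabling the
#'   evaluation-time filter.
#' @param cutoff minimum \code{|log2fc|} a variant must reach to enter
#'   evaluation (applied with \code{log2fc}).
#' @return data.frame with one row per evaluated fold: \code{fold, n_test,
#'   auroc, auprc}, plus attributes \code{lambda} and \code{skipped_folds}.
#' @export
eqtl_crossval <- function(features, labels, folds,
                          lambda_grid = 10^seq(-3, 2, by = 0.5),
                          tune_features = NULL, tune_labels = NULL,
                          log2fc = NULL, cutoff = NULL) {
  fold_id <- if (inherits(folds, "GroupedFolds")) folds$fold else folds
  stopifnot(nrow(features) == length(labels),
            length(fold_id) == length(labels))
  keep_eval <- rep(TRUE, length(labels))
  if (!is.null(cutoff)) {
    if (is.null(log2fc)) stop("cutoff filter requires log2fc values")
    keep_eval <- abs(log2fc) >= cutoff
    if (!any(keep_eval))
      stop(sprintf("no variant passes the filter |log2fc| >= %g", cutoff))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  pick_lambda <- function(x, y) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda_grid)
    if (!is.null(tune_features)) {
      pr <- stats::predict(fit, as.matrix(tune_features), type = "response")
      scores <- apply(pr, 2, function(p) auroc(p, tune_labels))
      return(fit$lambda[which.max(scores)])
    }
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = lambda_grid, nfolds = 5,
                            foldid = rep_len(1:5, length(y)))
    cv$lambda.min
  }
  rows <- list(); skipped <- integer()
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    te <- fold_id == f & keep_eval
    if (length(unique(labels[tr])) < 2 || length(unique(labels[te])) < 2) {
      warning("fold ", f, " skipped: single-class training or test labels")
      skipped <- c(skipped, f)
      next
    }
    lam <- pick_lambda(as.matrix(features[tr, , drop = FALSE]), labels[tr])
    fit <- glmnet::glmnet(as.matrix(features[tr, , drop = FALSE]),
                          labels[tr], family = "binomial", alpha = 0,
                          lambda = lambda_grid)
    p <- as.numeric(stats::predict(fit,
                                   as.matrix(features[te, , drop = FALSE]),
                                   s = lam, type = "response"))
    rows[[length(rows) + 1L]] <-
      data.frame(fold = f, n_test = sum(te), auroc = auroc(p, labels[te]),
                 auprc = auprc(p, labels[te]), lambda = lam)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped_folds") <- skipped
  out
}

# ---- Siamese few-shot pathogenicity classifier ------------------------------

#' Fit the Siamese few-shot pathogenicity classifier
#'
#' Two weight-tied copies of the multimodal encoder score the reference and
#' alternate windows; the squared differences of the event probabilities
#' (magnitude-only, hence invariant to input order) feed a fresh
#' events-to-1 fully connected layer with sigmoid output. Training is end
#' to end with cross-entropy plus L2 (default weight 1e-11, the tuned
#' optimum of the 1e-12..1e-8 sweep), early stopping on validation loss;
#' all parameters but the final layer are warm-started from the supplied
#' model. With zero training variants the zero-shot scorer is returned
#' instead.
#'
#' @param model a trained \code{MultimodalModel} (the warm start).
#' @param train_data list with window-sequence vectors \code{ref}, \code{alt},
#'   0-based \code{bins}, binary \code{y}; may have zero rows.
#' @param valid_data same shape, non-empty (ignored for zero-shot).
#' @param l2_weight L2 penalty weight (default 1e-11).
#' @param config a \code{\link{train_config}} (epochs, patience, lr, seed).
#' @return a \code{SiameseClassifier}.
#' @export
fit_siamese <- function(model, train_data, valid_data, l2_weight = 1e-11,
                        config = train_config(learning_rate = 1e-3,
                                              max_epochs = 20L,
                                              batch_size = 32L)) {
  n <- length(train_data$y %||% integer())
  if (n == 0L)
    return(structure(list(type = "zero_shot", model = model),
                     class = "SiameseClassifier"))
  set.seed(config$seed)
  head <- dense_init(model$n_events, 1L)
  sc <- structure(list(type = "siamese", model = model, head = head),
                  class = "SiameseClassifier")
  params <- list(enc = model$params, head = head)
  state <- adam_init(params)
  Xr <- onehot_windows(train_data$ref)
  Xa <- onehot_windows(train_data$alt)
  Vr <- onehot_windows(valid_data$ref)
  Va <- onehot_windows(valid_data$alt)
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      fr <- model_forward(model, Xr[idx, , , drop = FALSE],
                          train_data$bins[idx], train = FALSE,
                          params = params$enc)
      fa <- model_forward(model, Xa[idx, , , drop = FALSE],
                          train_data$bins[idx], train = FALSE,
                          params = params$enc)
      d2 <- (fr$probs - fa$probs)^2
      hd <- dense_fwd(d2, params$head)
      prob <- sigmoid(hd$out[, 1])
      y <- train_data$y[idx]
      dlogit <- matrix((prob - y) / length(idx), ncol = 1)
      hb <- dense_bwd(dlogit, hd$cache, params$head)
      dd2 <- hb$dX
      dp_r <- dd2 * 2 * (fr$probs - fa$probs)
      # chain through each tower's output sigmoid
      dz_r <- dp_r * fr$probs * (1 - fr$probs)
      dz_a <- -dp_r * fa$probs * (1 - fa$probs)
      genc <- params_add(
        model_backward(model, fr$cache, dz_r, params$enc),
        model_backward(model, fa$cache, dz_a, params$enc))
      grads <- params_reg_grad(list(enc = genc, head = hb$grads),
                               params, 0, l2_weight)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    vp <- siamese_scores(model, params, Vr, Va, valid_data$bins)
    vl <- bce_loss(matrix(vp, ncol = 1),
                   matrix(valid_data$y, ncol = 1)) +
      reg_penalty(params, 0, l2_weight)
    if (!is.finite(vl)) stop("non-finite Siamese validation loss")
    if (vl < best$loss) best <- list(loss = vl, params = params,
                                     epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  sc$model$params <- best$params$enc
  sc$head <- best$params$head
  sc
}

siamese_scores <- function(model, params, Xr, Xa, bins,
                           batch_size = 256L) {
  n <- dim(Xr)[1]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    pr <- model_forward(model, Xr[s:e, , , drop = FALSE], bins[s:e],
                        train = FALSE, params = params$enc)$probs
    pa <- model_forward(model, Xa[s:e, , , drop = FALSE], bins[s:e],
                        train = FALSE, params = params$enc)$probs
    d2 <- (pr - pa)^2
    out[s:e] <- sigmoid(dense_fwd(d2, params$head)$out[, 1])
  }
  out
}

#' Score variants with a Siamese (or zero-shot) classifier
#'
#' Output is exactly invariant to swapping the reference and alternate
#' inputs, because only squared probability differences enter the head.
#'
#' @param classifier a \code{SiameseClassifier} from \code{\link{fit_siamese}}.
#' @param ref,alt window-sequence vectors.
#' @param bins 0-based bin indices.
#' @return numeric pathogenicity scores (probabilities for the trained
#'   classifier; mean absolute probability differences for zero-shot).
#' @export
siamese_predict <- function(classifier, ref, alt, bins = NULL) {
  Xr <- onehot_windows(ref)
  Xa <- onehot_windows(alt)
  if (classifier$type == "zero_shot") {
    pr <- predict_profile(classifier$model, Xr, bins)
    pa <- predict_profile(classifier$model, Xa, bins)
    return(rowMeans(abs(pa - pr)))
  }
  siamese_scores(classifier$model,
                 list(enc = classifier$model$params, head = classifier$head),
                 Xr, Xa, bins)
}
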