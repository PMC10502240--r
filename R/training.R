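# Training loop (BCE + L1 + L2, Adam, early stopping, warm start) and the
# evaluation metrics used throughout (per-event AUROC/AUPRC, macro means).

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param l1_coef,l2_coef regularization coefficients applied to all weight
#'   matrices (biases exempt).
#' @param max_epochs maximum epochs (default 40).
#' @param patience early-stopping patience in epochs (default 4).
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization order, shuffling and
#'   dropout; two runs with the same seed produce identical histories.
#' @param warm_start optional checkpoint directory whose sequence-encoder
#'   parameters initialize this model's sequence encoder.
#' @param n_trials conventional number of independent training repeats for
#'   mean/sd reporting (default 5); consumed by callers, not by
#'   \code{train_model} itself.
#' @return a \code{TrainConfig} list.
#' @export
train_config <- function(learning_rate = 1e-3, l1_coef = 0, l2_coef = 0,
                         max_epochs = 40L, patience = 4L, batch_size = 64L,
                         seed = 0L, warm_start = NULL, n_trials = 5L) {
  if (patience > max_epochs) stop("patience must not exceed max_epochs")
  if (l1_coef < 0 || l2_coef < 0) stop("regularization coefficients must be >= 0")
  structure(list(learning_rate = learning_rate, l1_coef = l1_coef,
                 l2_coef = l2_coef, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 warm_start = warm_start, n_trials = as.integer(n_trials)),
            class = "TrainConfig")
}

#' Binary cross-entropy loss
#'
#' Mean over all (sample, event) entries; predictions are clipped to
#' \code{[1e-7, 1 - 1e-7]} before the log.
#'
#' @param pred probability matrix.
#' @param label binary matrix of the same shape.
#' @return scalar loss.
#' @export
bce_loss <- function(pred, label) {
  if (!all(dim(pred) == dim(label))) stop("pred/label shape mismatch")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

#' Full training loss: BCE plus L1 and L2 penalties
#'
#' @param pred,label as in \code{\link{bce_loss}}.
#' @param params parameter tree (weight leaves penalized, biases exempt).
#' @param l1_coef,l2_coef penalty coefficients.
#' @return scalar loss.
#' @export
training_loss <- function(pred, label, params, l1_coef = 0, l2_coef = 0) {
  bce_loss(pred, label) + reg_penalty(params, l1_coef, l2_coef)
}

reg_penalty <- function(params, l1_coef, l2_coef) {
  out <- 0
  if (l1_coef > 0) out <- out + l1_coef * params_penalty(params, function(w) sum(abs(w)))
  if (l2_coef > 0) out <- out + l2_coef * params_penalty(params, function(w) sum(w^2))
  out
}

valid_loss_of <- function(model, data, l1, l2, batch_size) {
  probs <- predict_profile(model, data$X, data$bins, batch_size)
  training_loss(probs, data$Y, model$params, l1, l2)
}

#' Train a multimodal model
#'
#' Adam on binary cross-entropy with L1/L2 regularization, early stopping on
#' validation loss with the configured patience, returning the
#' best-validation checkpoint (never the last epoch). An optional warm start
#' loads sequence-encoder parameters from a pretrained sequence-only
#' checkpoint.
#'
#' @param model a \code{MultimodalModel}.
#' @param train_data,valid_data lists with one-hot array \code{X}
#'   (n, L, 4), 0-based \code{bins} and binary label matrix \code{Y}
#'   (n x n_events).
#' @param config a \code{\link{train_config}}.
#' @return list with \code{model} (best parameters), \code{history}
#'   (data.frame epoch/train_loss/valid_loss), \code{best_epoch} and
#'   \code{stopped_epoch}.
#' @export
train_model <- function(model, train_data, valid_data, config) {
  stopifnot(inherits(config, "TrainConfig"))
  if (ncol(train_data$Y) != model$n_events)
    stop(sprintf("label matrix has %d events but model emits %d",
                 ncol(train_data$Y), model$n_events))
  if (is.null(valid_data) || dim(valid_data$X)[1] == 0)
    stop("validation set must be non-empty")
  set.seed(config$seed)
  if (!is.null(config$warm_start))
    model <- load_checkpoint(config$warm_start, model, sequence_only = TRUE)
  n <- dim(train_data$X)[1]
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     valid_loss = numeric())
  stopped <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      Xb <- train_data$X[idx, , , drop = FALSE]
      Yb <- train_data$Y[idx, , drop = FALSE]
      fw <- model_forward(model, Xb, train_data$bins[idx], train = TRUE)
      bl <- bce_loss(fw$probs, Yb)
      if (!is.finite(bl))
        stop("NaN/Inf training loss at epoch ", epoch,
             ": learning rate likely too high")
      dlogits <- (fw$probs - Yb) / length(Yb)
      grads <- model_backward(model, fw$cache, dlogits)
      grads <- params_reg_grad(grads, model$params,
                               config$l1_coef, config$l2_coef)
      upd <- adam_step(model$params, grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      tot <- tot + bl * length(idx)
    }
    train_loss <- tot / n + reg_penalty(model$params, config$l1_coef,
                                        config$l2_coef)
    valid_loss <- valid_loss_of(model, valid_data, config$l1_coef,
                                config$l2_coef, config$batch_size)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   valid_loss = valid_loss))
    if (valid_loss < best$loss)
      best <- list(loss = valid_loss, params = model$params, epoch = epoch)
    if (epoch - best$epoch >= config$patience) { stopped <- epoch; break }
  }
  model$params <- best$params
  list(model = model, history = hist, best_epoch = best$epoch,
       stopped_epoch = stopped)
}

# ---- metrics ----------------------------------------------------------------

#' Area under the ROC curve
#'
#' Computed by pair counting: the probability that a positive outscores a
#' negative, ties counting one half (equivalently the rank-sum form).
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return AUROC in \code{[0,1]}, or \code{NA} if labels are degenerate.
#' @export
auroc <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise integral in the average-precision convention:
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} over distinct score thresholds in
#' decreasing order, which is tie-safe and equals the random baseline
#' (the positive rate) in expectation for uninformative scores.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return AUPRC in \code{(0,1]}, or \code{NA} if labels are degenerate.
#' @export
auprc <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # last index of each distinct-score block = the threshold operating points
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Per-event metrics with macro averages
#'
#' Events with no positive or no negative label in the evaluation set are
#' excluded from the macro means and listed.
#'
#' @param probs (n x E) score matrix.
#' @param labels (n x E) binary matrix.
#' @return a \code{MetricsReport}: data.frame \code{per_event} (event,
#'   auroc, auprc), \code{macro_auroc}, \code{macro_auprc},
#'   \code{excluded_events}.
#' @export
metrics_report <- function(probs, labels) {
  stopifnot(all(dim(probs) == dim(labels)))
  E <- ncol(labels)
  per <- data.frame(event = seq_len(E),
                    auroc = vapply(seq_len(E), function(e)
                      auroc(probs[, e], labels[, e]), numeric(1)),
                    auprc = vapply(seq_len(E), function(e)
                      auprc(probs[, e], labels[, e]), numeric(1)))
  ok <- !is.na(per$auroc)
  structure(list(per_event = per,
                 macro_auroc = mean(per$auroc[ok]),
                 macro_auprc = mean(per$auprc[ok]),
                 excluded_events = per$event[!ok]),
            class = "MetricsReport")
}

#' @exportS3Method print MetricsReport
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport: macro AUROC %.4f, macro AUPRC %.4f (%d/%d events)\n",
              x$macro_auroc, x$macro_auprc,
              nrow(x$per_event) - length(x$excluded_events),
              nrow(x$per_event)))
  invisible(x)
}

#' Write per-event metrics to TSV
#'
#' @param report a \code{MetricsReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(report, path) {
  utils::write.table(report$per_event, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
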