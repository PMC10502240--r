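# Disparity analysis: do chromatin interaction frequencies explain sample
# pairs whose DNA sequence similarity and epigenetic profile similarity
# disagree?

#' Sequence similarity between two equal-length windows
#'
#' The default metric is positional identity over comparable positions:
#' the fraction of positions where both sequences carry the same non-N base,
#' among positions where neither is N (0 when no position is comparable).
#' A k-mer cosine alternative is available as a strategy option.
#'
#' @param s1,s2 equal-length DNA strings.
#' @param metric \code{"identity"} or \code{"kmer_cosine"}.
#' @param k k-mer size for the cosine metric.
#' @return similarity in \code{[0,1]}.
#' @export
sequence_similarity <- function(s1, s2, metric = c("identity", "kmer_cosine"),
                                k = 4L) {
  metric <- match.arg(metric)
  if (nchar(s1) != nchar(s2)) stop("sequences must have equal length")
  if (metric == "identity") {
    a <- strsplit(s1, "", fixed = TRUE)[[1]]
    b <- strsplit(s2, "", fixed = TRUE)[[1]]
    ok <- a != "N" & b != "N"
    if (!any(ok)) return(0)
    return(mean(a[ok] == b[ok]))
  }
  ca <- kmer_counts(s1, k); cb <- kmer_counts(s2, k)
  na <- sqrt(sum(ca^2)); nb <- sqrt(sum(cb^2))
  if (na == 0 || nb == 0) return(0)
  sum(ca * cb) / (na * nb)
}

#' k-mer count vector of a sequence
#'
#' Counts the \code{4^k} possible k-mers over \code{A,C,G,T}; windows
#' containing \code{N} are skipped.
#'
#' @param sequence DNA string.
#' @param k k-mer size (1..8).
#' @return integer vector of length \code{4^k} named by k-mer.
#' @export
kmer_counts <- function(sequence, k = 4L) {
  if (k < 1 || k > 8) stop("k must be in 1..8")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = k)
  as.integer(counts)
}

#' Profile similarity between two binary label vectors
#'
#' Jaccard index by default; cosine as a strategy option. Undefined (error)
#' when both profiles are all-zero under Jaccard — such pairs are excluded
#' upstream.
#'
#' @param p1,p2 equal-length binary vectors.
#' @param metric \code{"jaccard"} or \code{"cosine"}.
#' @return similarity in \code{[0,1]}.
#' @export
profile_similarity <- function(p1, p2, metric = c("jaccard", "cosine")) {
  metric <- match.arg(metric)
  if (length(p1) != length(p2)) stop("profiles must have equal length")
  if (metric == "jaccard") {
    un <- sum(p1 | p2)
    if (un == 0) stop("profile similarity undefined: both profiles all-zero")
    return(sum(p1 & p2) / un)
  }
  n1 <- sqrt(sum(p1^2)); n2 <- sqrt(sum(p2^2))
  if (n1 == 0 || n2 == 0) stop("cosine profile similarity undefined for zero vector")
  sum(p1 * p2) / (n1 * n2)
}

#' Partition sample pairs by similarity-percentile disparity
#'
#' Sequence and profile similarities of the supplied pairs are converted to
#' percentile ranks within the pair set (average rank for ties). A pair is
#' \emph{over} when its sequence percentile exceeds its profile percentile by
#' more than \code{margin} points, \emph{under} when it lags by more than
#' \code{margin}, and \emph{consistent} otherwise.
#'
#' @param pairs data.frame with numeric columns \code{seq_sim},
#'   \code{prof_sim} and nonnegative \code{freq}.
#' @param margin percentile-point margin in \code{(0,100]}; 100 is the
#'   degenerate bound classifying every pair as consistent.
#' @return a list of class \code{PartitionResult} with integer row-index
#'   vectors \code{over}, \code{consistent}, \code{under}, the computed
#'   percentiles, and \code{margin}.
#' @export
percentile_partition <- function(pairs, margin = 10) {
  if (margin <= 0 || margin > 100) stop("margin must be in (0,100]")
  if (nrow(pairs) < 2) stop("need at least 2 pairs to rank")
  if (any(pairs$freq < 0)) stop("frequencies must be nonnegative")
  n <- nrow(pairs)
  seq_pct <- 100 * rank(pairs$seq_sim, ties.method = "average") / n
  prof_pct <- 100 * rank(pairs$prof_sim, ties.method = "average") / n
  d <- seq_pct - prof_pct
  structure(list(over = which(d > margin),
                 consistent = which(abs(d) <= margin),
                 under = which(d < -margin),
                 seq_pct = seq_pct, prof_pct = prof_pct,
                 margin = margin),
            class = "PartitionResult")
}

#' One-sided Wilcoxon rank-sum test
#'
#' Tests the location of sample \code{x} against sample \code{y} using the
#' rank-sum statistic with mid-ranks for ties. For combined sample sizes up
#' to \code{exact_limit} the p-value is exact, by enumeration of all
#' assignments of the pooled observed values (ties included) to the two
#' groups; beyond that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative \code{"greater"} (x located above y) or \code{"less"}.
#' @param exact_limit largest \code{length(x)+length(y)} for exact
#'   enumeration (default 12).
#' @return the one-sided p-value.
#' @export
rank_sum_one_sided <- function(x, y, alternative = c("greater", "less"),
                               exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  w <- sum(r[seq_len(nx)])
  eps <- 1e-9
  if (n <= exact_limit) {
    sets <- utils::combn(n, nx)
    ws <- colSums(matrix(r[sets], nrow = nx))
    if (alternative == "greater") return(mean(ws >= w - eps))
    return(mean(ws <= w + eps))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)  # all values identical: no evidence either way
  s <- sqrt(sigma2)
  if (alternative == "greater") {
    stats::pnorm((w - mu - 0.5) / s, lower.tail = FALSE)
  } else {
    stats::pnorm((w - mu + 0.5) / s, lower.tail = TRUE)
  }
}

#' Run the sequence-profile disparity test
#'
#' For each repeat, a fraction \code{frac} of the windows is drawn without
#' replacement; all pairs among the drawn windows with a nonzero chromatin
#' interaction frequency (raw matrix entry between the windows' bins) and a
#' defined profile similarity are scored for sequence and profile
#' similarity, partitioned by percentile disparity, and two one-sided
#' rank-sum tests are performed: whether the \emph{under} pairs' interaction
#' frequencies exceed the \emph{consistent} pairs' (alternative
#' \code{greater}), and whether the \emph{over} pairs' fall below the
#' \emph{consistent} pairs' (alternative \code{less}).
#'
#' @param seqs character vector of window sequences (equal length).
#' @param profiles binary matrix, one row per window, one column per event.
#' @param bins 0-based global bin index per window.
#' @param matrix an \code{InteractionMatrix} covering the bins.
#' @param frac fraction of windows sampled per repeat (default 0.02).
#' @param repeats number of repeats (default 3).
#' @param margin percentile margin for the partition (default 10).
#' @param seed integer seed driving all repeats.
#' @param seq_metric,profile_metric similarity strategies, see
#'   \code{\link{sequence_similarity}} and \code{\link{profile_similarity}}.
#' @return a \code{TestReport} list: data.frame \code{repeats} with columns
#'   \code{repeat_id, n_pairs, n_under, n_consistent, n_over, p_under,
#'   p_over}, plus \code{sig_freq_under}, \code{sig_freq_over} (frequency of
#'   p < .05 among non-NA repeats), \code{frac}, \code{margin}, \code{seed}.
#' @export
run_disparity_test <- function(seqs, profiles, bins, matrix,
                               frac = 0.02, repeats = 3L, margin = 10,
                               seed = 1L,
                               seq_metric = "identity",
                               profile_metric = "jaccard") {
  n <- length(seqs)
  stopifnot(nrow(profiles) == n, length(bins) == n)
  m <- floor(frac * n)
  if (m < 2)
    stop(sprintf("frac=%g draws %d windows; need >= 2 - increase frac",
                 frac, m))
  vals <- matrix$values
  rows <- vector("list", repeats)
  set.seed(seed)
  for (rep_id in seq_len(repeats)) {
    idx <- sample.int(n, m)
    pr <- t(utils::combn(idx, 2))
    freq <- as.numeric(vals[cbind(bins[pr[, 1]] + 1L, bins[pr[, 2]] + 1L)])
    defined <- rowSums(cbind(profiles[pr[, 1], , drop = FALSE] +
                               profiles[pr[, 2], , drop = FALSE])) > 0
    keep <- freq > 0 & defined
    pr <- pr[keep, , drop = FALSE]; freq <- freq[keep]
    if (nrow(pr) < 2) {
      rows[[rep_id]] <- data.frame(repeat_id = rep_id, n_pairs = nrow(pr),
                                   n_under = NA, n_consistent = NA,
                                   n_over = NA, p_under = NA, p_over = NA)
      next
    }
    seq_sim <- vapply(seq_len(nrow(pr)), function(q)
      sequence_similarity(seqs[pr[q, 1]], seqs[pr[q, 2]], seq_metric),
      numeric(1))
    prof_sim <- vapply(seq_len(nrow(pr)), function(q)
      profile_similarity(profiles[pr[q, 1], ], profiles[pr[q, 2], ],
                         profile_metric), numeric(1))
    part <- percentile_partition(
      data.frame(seq_sim = seq_sim, prof_sim = prof_sim, freq = freq),
      margin = margin)
    p_under <- if (length(part$under) > 0 && length(part$consistent) > 0)
      rank_sum_one_sided(freq[part$under], freq[part$consistent], "greater")
    else NA_real_
    p_over <- if (length(part$over) > 0 && length(part$consistent) > 0)
      rank_sum_one_sided(freq[part$over], freq[part$consistent], "less")
    else NA_real_
    rows[[rep_id]] <- data.frame(repeat_id = rep_id, n_pairs = nrow(pr),
                                 n_under = length(part$under),
                                 n_consistent = length(part$consistent),
                                 n_over = length(part$over),
                                 p_under = p_under, p_over = p_over)
  }
  rep_df <- do.call(rbind, rows)
  sig_freq <- function(p) if (all(is.na(p))) NA_real_ else
    mean(p[!is.na(p)] < 0.05)
  structure(list(repeats = rep_df,
                 sig_freq_under = sig_freq(rep_df$p_under),
                 sig_freq_over = sig_freq(rep_df$p_over),
                 frac = frac, margin = margin, seed = seed),
            class = "TestReport")
}

#' @exportS3Method print TestReport
print.TestReport <- function(x, ...) {
  cat(sprintf("Disparity TestReport: %d repeat(s), frac=%g, margin=%g\n",
              nrow(x$repeats), x$frac, x$margin))
  print(x$repeats, row.names = FALSE)
  cat(sprintf("frequency of p<.05: under %s, over %s\n",
              format(x$sig_freq_under), format(x$sig_freq_over)))
  invisible(x)
}

#' Write a disparity TestReport to TSV
#'
#' @param report a \code{TestReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_test_report <- function(report, path) {
  utils::write.table(report$repeats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Spearman agreement between true and predicted label similarities
#'
#' Randomly samples window pairs, computes true-profile similarity (Jaccard)
#' and predicted similarity (the same metric on predictions thresholded at
#' 0.5, or cosine on the raw probability vectors), and reports the Spearman
#' rank correlation; when sequences are supplied, the correlation is
#' additionally reported within each disparity-partition cell.
#'
#' @param true_profiles binary matrix (windows x events).
#' @param predicted_probs numeric matrix of the same shape in \code{[0,1]}.
#' @param n_pairs number of pairs to sample (>= 3).
#' @param seed integer seed.
#' @param seqs optional window sequences enabling the per-cell breakdown.
#' @param margin partition margin when \code{seqs} is given.
#' @param pred_metric \code{"threshold_jaccard"} or \code{"cosine"}.
#' @return a list with \code{rho_all} and, when \code{seqs} is given,
#'   \code{rho_over}, \code{rho_consistent}, \code{rho_under} (NA when a
#'   similarity vector is constant or a cell has < 3 pairs).
#' @export
label_similarity_spearman <- function(true_profiles, predicted_probs,
                                      n_pairs = 1000L, seed = 1L,
                                      seqs = NULL, margin = 10,
                                      pred_metric = c("threshold_jaccard",
                                                      "cosine")) {
  pred_metric <- match.arg(pred_metric)
  if (n_pairs < 3) stop("n_pairs must be >= 3")
  n <- nrow(true_profiles)
  stopifnot(all(dim(true_profiles) == dim(predicted_probs)))
  set.seed(seed)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n, n_pairs, replace = TRUE)
  fix <- i == j
  j[fix] <- (j[fix] %% n) + 1L
  keep <- rowSums(true_profiles[i, , drop = FALSE] +
                    true_profiles[j, , drop = FALSE]) > 0
  i <- i[keep]; j <- j[keep]
  true_sim <- vapply(seq_along(i), function(q)
    profile_similarity(true_profiles[i[q], ], true_profiles[j[q], ]),
    numeric(1))
  pred_sim <- vapply(seq_along(i), function(q) {
    if (pred_metric == "threshold_jaccard") {
      a <- as.integer(predicted_probs[i[q], ] >= 0.5)
      b <- as.integer(predicted_probs[j[q], ] >= 0.5)
      un <- sum(a | b)
      if (un == 0) return(0)
      sum(a & b) / un
    } else {
      profile_similarity(predicted_probs[i[q], ], predicted_probs[j[q], ],
                         metric = "cosine")
    }
  }, numeric(1))
  rho <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b, method = "spearman")
  }
  out <- list(rho_all = rho(true_sim, pred_sim), n_pairs_used = length(i))
  if (!is.null(seqs)) {
    seq_sim <- vapply(seq_along(i), function(q)
      sequence_similarity(seqs[i[q]], seqs[j[q]]), numeric(1))
    part <- percentile_partition(
      data.frame(seq_sim = seq_sim, prof_sim = true_sim, freq = 0),
      margin = margin)
    out$rho_over <- rho(true_sim[part$over], pred_sim[part$over])
    out$rho_consistent <- rho(true_sim[part$consistent],
                              pred_sim[part$consistent])
    out$rho_under <- rho(true_sim[part$under], pred_sim[part$under])
  }
  out
}
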