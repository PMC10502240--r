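# Kernel interpretation: convert first-layer convolution kernels into
# position-specific frequency matrices (PSFMs) from their max-activating
# test subsequences, and export them in MEME minimal motif format.

#' Max-activating placement of a kernel on a window
#'
#' Slides the kernel (cross-correlation, no bias) over the one-hot window
#' and returns the offset of the largest activation; ties break to the
#' smallest offset.
#'
#' @param kernel a (k x 4) matrix, positions by bases A,C,G,T.
#' @param window a window sequence (string) or 4 x L one-hot matrix.
#' @return list with \code{offset} (0-based) and \code{activation}.
#' @export
max_activation_window <- function(kernel, window) {
  oh <- if (is.character(window)) one_hot(window) else window
  k <- nrow(kernel); L <- ncol(oh)
  if (k > L) stop("kernel wider than window")
  X <- array(0, dim = c(1L, L, 4L))
  X[1, , ] <- t(oh)
  act <- conv1d_fwd(X, list(W = array(kernel, c(k, 4L, 1L)),
                            b = 0))$out[1, , 1]
  o <- which.max(act)  # first maximum = leftmost tie
  list(offset = o - 1L, activation = act[o])
}

#' Build a PSFM for one kernel from qualifying windows
#'
#' For every window whose maximal activation exceeds the threshold, the
#' max-activating k-base subsequence is stacked; column-wise base
#' frequencies with a pseudocount per cell give the profile.
#'
#' @param kernel a (k x 4) matrix.
#' @param test_windows character vector of window sequences.
#' @param activation_threshold minimum max-activation for a window to
#'   contribute (default 0, positive-activation gating).
#' @param alpha pseudocount added to each cell (default 0.001).
#' @param kernel_id identifier stored in the result.
#' @return a \code{MotifPSFM} (fields \code{kernel_id}, \code{width},
#'   \code{probs} 4 x width with unit column sums, \code{nsites}), or
#'   \code{NULL} if no window qualifies (inactive kernel).
#' @export
build_psfm <- function(kernel, test_windows, activation_threshold = 0,
                       alpha = 0.001, kernel_id = NA) {
  k <- nrow(kernel)
  counts <- matrix(0, 4, k, dimnames = list(BASES, NULL))
  nsites <- 0L
  for (w in test_windows) {
    hit <- max_activation_window(kernel, w)
    if (hit$activation > activation_threshold) {
      sub <- substr(w, hit$offset + 1L, hit$offset + k)
      counts <- counts + one_hot(sub)
      nsites <- nsites + 1L
    }
  }
  if (nsites == 0L) return(NULL)
  probs <- sweep(counts + alpha, 2, colSums(counts + alpha), "/")
  structure(list(kernel_id = kernel_id, width = k, probs = probs,
                 nsites = nsites), class = "MotifPSFM")
}

#' Extract PSFMs for every first-layer kernel of a model
#'
#' Scans all first-convolution kernels (320 at published scale) over the
#' supplied test windows in one batched pass and builds a PSFM per kernel
#' from max-activating subsequences; kernels that never activate above the
#' threshold are reported as inactive.
#'
#' @param model a \code{MultimodalModel} (or \code{SequenceEncoder}).
#' @param test_windows character vector of window sequences.
#' @param activation_threshold,alpha see \code{\link{build_psfm}}.
#' @param batch_size windows per scanning batch.
#' @return list with \code{psfms} (list of \code{MotifPSFM}),
#'   \code{n_kernels} and \code{inactive_kernels} (integer ids).
#' @export
extract_motifs <- function(model, test_windows, activation_threshold = 0,
                           alpha = 0.001, batch_size = 128L) {
  params <- if (inherits(model, "MultimodalModel")) model$params$seq
            else model$params
  W <- params$conv1$W                     # (k, 4, K)
  k <- dim(W)[1]; K <- dim(W)[3]
  counts <- array(0, dim = c(4, k, K))
  nsites <- integer(K)
  n <- length(test_windows)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    seqs <- test_windows[s:e]
    X <- onehot_windows(seqs)
    act <- conv1d_fwd(X, list(W = W, b = numeric(K)))$out  # (nb, Lout, K)
    nb <- dim(act)[1]
    for (f in seq_len(K)) {
      a <- act[, , f, drop = FALSE]; dim(a) <- dim(act)[1:2]
      off <- max.col(a, ties.method = "first")
      mx <- a[cbind(seq_len(nb), off)]
      use <- which(mx > activation_threshold)
      for (q in use) {
        sub <- substr(seqs[q], off[q], off[q] + k - 1L)
        counts[, , f] <- counts[, , f] + one_hot(sub)
        nsites[f] <- nsites[f] + 1L
      }
    }
  }
  psfms <- list()
  for (f in seq_len(K)) {
    if (nsites[f] == 0L) next
    cm <- counts[, , f] + alpha
    probs <- sweep(cm, 2, colSums(cm), "/")
    dimnames(probs) <- list(BASES, NULL)
    psfms[[length(psfms) + 1L]] <-
      structure(list(kernel_id = f, width = k, probs = probs,
                     nsites = nsites[f]), class = "MotifPSFM")
  }
  list(psfms = psfms, n_kernels = K,
       inactive_kernels = which(nsites == 0L))
}

#' Information content per PSFM column
#'
#' @param psfm a \code{MotifPSFM}.
#' @return numeric vector of bits per column (2 minus column entropy).
#' @export
psfm_information <- function(psfm) {
  apply(psfm$probs, 2, function(p) 2 + sum(p * log2(p)))
}

#' Convert window sequences to a one-hot batch array
#'
#' @param seqs character vector of equal-length sequences.
#' @return array (n, L, 4) with base order A,C,G,T.
#' @export
onehot_windows <- function(seqs) {
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stop("windows must have equal length")
  n <- length(seqs)
  X <- array(0, dim = c(n, L, 4L))
  for (i in seq_len(n)) X[i, , ] <- t(one_hot(seqs[i]))
  X
}

# ---- MEME minimal motif format ---------------------------------------------

#' Export PSFMs in MEME minimal motif format (version 4)
#'
#' @param psfms list of \code{MotifPSFM} (may be empty: a valid header-only
#'   file is written).
#' @param path output path.
#' @param background base frequencies A,C,G,T (default uniform).
#' @return \code{path}, invisibly.
#' @export
export_meme <- function(psfms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (m in psfms) {
    writeLines(sprintf("MOTIF kernel_%s", m$kernel_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      m$width, m$nsites), con)
    for (j in seq_len(m$width))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m$probs[1, j],
                         m$probs[2, j], m$probs[3, j], m$probs[4, j]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal motif file
#'
#' Parses files written by \code{\link{export_meme}} (round-trip testing and
#' downstream reuse).
#'
#' @param path input path.
#' @return list of \code{MotifPSFM}.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines)))
    stop("not a MEME motif file: ", path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      id <- sub("^MOTIF\\s+", "", lines[i])
      hdr <- lines[i + 1L]
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
      ns <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
      probs <- matrix(0, 4, w, dimnames = list(BASES, NULL))
      for (j in seq_len(w))
        probs[, j] <- as.numeric(strsplit(trimws(lines[i + 1L + j]),
                                          "\\s+")[[1]])
      out[[length(out) + 1L]] <-
        structure(list(kernel_id = sub("^kernel_", "", id), width = w,
                       probs = probs, nsites = ns), class = "MotifPSFM")
      i <- i + w + 2L
    }
    i <- i + 1L
  }
  out
}
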