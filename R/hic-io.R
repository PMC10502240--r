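# ---- Bin grids --------------------------------------------------------------

#' Fixed-resolution genome bin grid
#'
#' Divides every chromosome of an assembly into contiguous bins of
#' \code{resolution} bases (the last bin of a chromosome may be partial) and
#' assigns global bin indices in chromosome order. The grid is the bridge
#' between base-resolution sequence windows and contact-map bins.
#'
#' @param assembly a \code{GenomeAssembly}, or a named vector of chromosome
#'   lengths.
#' @param resolution bases per bin (default 100000, the usual Hi-C working
#'   resolution; scaled down for desk-scale fixtures).
#' @return an object of class \code{BinGrid} with \code{resolution},
#'   \code{chrom_names}, \code{chrom_lengths}, \code{n_bins} (per
#'   chromosome), \code{offsets} (0-based global offset per chromosome) and
#'   \code{total_bins}.
#' @export
bin_grid <- function(assembly, resolution = 100000L) {
  lens <- if (inherits(assembly, "GenomeAssembly")) assembly$chrom_lengths
          else assembly
  if (is.null(names(lens))) stop("chromosome lengths must be named")
  if (resolution < 1) stop("resolution must be positive")
  nb <- as.integer(ceiling(lens / resolution))
  offsets <- cumsum(c(0L, nb[-length(nb)]))
  names(offsets) <- names(lens)
  structure(list(resolution = as.integer(resolution),
                 chrom_names = names(lens),
                 chrom_lengths = lens,
                 n_bins = stats::setNames(nb, names(lens)),
                 offsets = offsets,
                 total_bins = sum(nb)),
            class = "BinGrid")
}

#' @exportS3Method print BinGrid
print.BinGrid <- function(x, ...) {
  cat(sprintf("BinGrid: %d bins over %d chromosome(s) at %d bp/bin\n",
              x$total_bins, length(x$chrom_names), x$resolution))
  invisible(x)
}

#' Global bin index of a genomic position
#'
#' @param grid a \code{BinGrid}.
#' @param chrom chromosome name(s).
#' @param position 0-based position(s) within the chromosome. A sequence
#'   window is conventionally assigned by its center position.
#' @return 0-based global bin index (integer vector).
#' @export
bin_of <- function(grid, chrom, position) {
  off <- grid$offsets[chrom]
  if (anyNA(off)) stop("unknown chromosome: ",
                       paste(unique(chrom[is.na(off)]), collapse = ", "))
  if (any(position < 0) || any(position >= grid$chrom_lengths[chrom]))
    stop("position outside chromosome")
  as.integer(off + position %/% grid$resolution)
}

#' Bin index of a window's center
#'
#' @param grid a \code{BinGrid}.
#' @param intervals interval data.frame.
#' @return 0-based global bin indices.
#' @export
bin_of_window <- function(grid, intervals) {
  bin_of(grid, intervals$chrom,
         (intervals$start + intervals$end) %/% 2L)
}

# ---- Interaction matrices ---------------------------------------------------

#' Wrap a contact matrix over a grid
#'
#' @param grid a \code{BinGrid}.
#' @param values symmetric nonnegative matrix (dense or \code{Matrix}) of
#'   dimension \code{grid$total_bins}.
#' @return an \code{InteractionMatrix}.
#' @export
interaction_matrix <- function(grid, values) {
  if (nrow(values) != grid$total_bins || ncol(values) != grid$total_bins)
    stop("matrix dimension does not match grid bins")
  if (any(values < 0)) stop("interaction frequencies must be nonnegative")
  if (max(abs(values - Matrix::t(values))) > 1e-8)
    stop("interaction matrix must be symmetric")
  structure(list(grid = grid, values = values), class = "InteractionMatrix")
}

#' Read a whole-genome contact matrix
#'
#' Two text formats are supported: a dense tab-separated matrix of dimension
#' \code{total_bins}, or COO triplets with columns
#' \code{chromA startA chromB startB count}. Asymmetric input is symmetrized
#' by the elementwise maximum of the matrix and its transpose, which
#' tolerates upper-triangle-only files.
#'
#' @param path input path.
#' @param grid a \code{BinGrid}.
#' @param format \code{"coo"} or \code{"dense"}.
#' @return an \code{InteractionMatrix} (sparse \code{Matrix} storage).
#' @export
read_contacts <- function(path, grid, format = c("coo", "dense")) {
  format <- match.arg(format)
  n <- grid$total_bins
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != n || ncol(m) != n)
      stop(sprintf("dense matrix is %dx%d but grid has %d bins",
                   nrow(m), ncol(m), n))
    if (any(m < 0)) stop("negative contact count in ", path)
    vals <- Matrix::Matrix(pmax(m, t(m)), sparse = TRUE)
    return(interaction_matrix(grid, vals))
  }
  info <- file.info(path)
  if (is.na(info$size)) stop("contact file not found: ", path)
  if (info$size == 0)
    return(interaction_matrix(
      grid, Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(n, n))))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop("COO contact file needs 5 columns: ",
                         "chromA startA chromB startB count")
  if (any(df[[2]] %% grid$resolution != 0) ||
      any(df[[4]] %% grid$resolution != 0))
    stop("contact coordinates must be multiples of the grid resolution (",
         grid$resolution, ")")
  if (any(df[[5]] < 0)) stop("negative contact count in ", path)
  i <- bin_of(grid, df[[1]], df[[2]]) + 1L
  j <- bin_of(grid, df[[3]], df[[4]]) + 1L
  a <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(df[[5]]),
                            dims = c(n, n), use.last.ij = TRUE)
  vals <- pmax(a, Matrix::t(a))
  interaction_matrix(grid, vals)
}

#' Write a contact matrix as COO triplets
#'
#' Emits the upper triangle (including the diagonal) of nonzero entries in
#' row-major order, so write-then-read round-trips bit-exactly.
#'
#' @param matrix an \code{InteractionMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contacts <- function(matrix, path) {
  grid <- matrix$grid
  tri <- Matrix::summary(methods::as(
    Matrix::triu(Matrix::Matrix(matrix$values, sparse = TRUE)), "TsparseMatrix"))
  tri <- tri[tri$x != 0, , drop = FALSE]
  ord <- order(tri$i, tri$j)
  tri <- tri[ord, , drop = FALSE]
  gi <- tri$i - 1L; gj <- tri$j - 1L
  chrom_at <- function(g) {
    k <- findInterval(g, grid$offsets)
    grid$chrom_names[k]
  }
  start_at <- function(g) {
    k <- findInterval(g, grid$offsets)
    (g - grid$offsets[k]) * grid$resolution
  }
  out <- data.frame(chrom_at(gi), start_at(gi), chrom_at(gj), start_at(gj),
                    tri$x)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- Normalization and featurizations ---------------------------------------

#' Normalize a contact matrix
#'
#' Two schemes are offered, matched to the two structure-encoder families:
#' \describe{
#'   \item{\code{row}}{row-stochastic rows (each nonzero row divided by its
#'     sum; zero rows stay zero) for the per-bin MLP featurization.}
#'   \item{\code{sym_loop}}{symmetric self-loop normalization
#'     \eqn{D^{-1/2}(A + I)D^{-1/2}} of the \code{log1p}-transformed matrix,
#'     the standard graph-convolution propagation operator; bounded,
#'     symmetric, sparsity-preserving.}
#' }
#'
#' @param matrix an \code{InteractionMatrix}.
#' @param scheme \code{"row"} or \code{"sym_loop"}.
#' @return a list with \code{scheme} and \code{values}, class
#'   \code{NormalizedMatrix}.
#' @export
normalize_contacts <- function(matrix, scheme = c("row", "sym_loop")) {
  scheme <- match.arg(scheme)
  v <- Matrix::Matrix(matrix$values, sparse = TRUE)
  if (scheme == "row") {
    rs <- Matrix::rowSums(v)
    scale <- ifelse(rs > 0, 1 / rs, 0)
    out <- Matrix::Diagonal(x = scale) %*% v
  } else {
    a <- v
    a@x <- log1p(a@x)
    a <- a + Matrix::Diagonal(nrow(a))
    d <- Matrix::rowSums(a)
    dm <- Matrix::Diagonal(x = 1 / sqrt(d))
    out <- dm %*% a %*% dm
  }
  structure(list(scheme = scheme, values = out), class = "NormalizedMatrix")
}

#' Per-bin chromatin accessibility proxy
#'
#' Row sums of the raw interaction matrix, the 1D ablation featurization
#' (total contact read counts per bin).
#'
#' @param matrix an \code{InteractionMatrix}.
#' @return numeric vector over global bins.
#' @export
accessibility <- function(matrix) {
  as.numeric(Matrix::rowSums(matrix$values))
}

#' Sequential 1D regional-order graph
#'
#' Unit-weight chain adjacency linking consecutive bins within each
#' chromosome and nothing across chromosomes: the 1D ablation of the 3D
#' contact graph.
#'
#' @param grid a \code{BinGrid}.
#' @return an \code{InteractionMatrix} holding the chain adjacency.
#' @export
sequential_graph <- function(grid) {
  n <- grid$total_bins
  ii <- integer(0); jj <- integer(0)
  for (k in seq_along(grid$chrom_names)) {
    nb <- grid$n_bins[k]
    if (nb >= 2) {
      s <- grid$offsets[k] + seq_len(nb - 1L)   # 1-based row index of bin b
      ii <- c(ii, s); jj <- c(jj, s + 1L)
    }
  }
  vals <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                               x = rep(1, 2 * length(ii)), dims = c(n, n))
  interaction_matrix(grid, vals)
}
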