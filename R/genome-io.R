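# ---- Genome assemblies ------------------------------------------------------

#' Construct a genome assembly from named DNA sequences
#'
#' An assembly is the fixed substrate every other component indexes into:
#' chromosome order is significant and reused for bin indexing, so it is
#' frozen at construction.
#'
#' @param seqs named character vector of DNA sequences. Sequences are
#'   uppercased and any character outside \code{A,C,G,T,N} is mapped to
#'   \code{N}.
#' @return an object of class \code{GenomeAssembly} with fields
#'   \code{chrom_names}, \code{chrom_seqs} (named), \code{chrom_lengths}
#'   (named, in bases).
#' @export
genome_assembly <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyDuplicated(names(seqs)))
    stop("sequences must have unique non-empty names")
  seqs <- toupper(seqs)
  seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  structure(
    list(chrom_names = names(seqs),
         chrom_seqs = seqs,
         chrom_lengths = vapply(seqs, nchar, integer(1))),
    class = "GenomeAssembly")
}

#' @exportS3Method print GenomeAssembly
print.GenomeAssembly <- function(x, ...) {
  cat(sprintf("GenomeAssembly: %d chromosome(s), %s bases total\n",
              length(x$chrom_names),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ",")))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and ambiguity codes (anything outside
#' \code{A,C,G,T,N}) are collapsed to \code{N}.
#'
#' @param path path to a FASTA file.
#' @return a \code{\link{genome_assembly}}.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dss <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  seqs <- as.character(dss)
  names(seqs) <- sub("\\s.*$", "", names(dss))
  genome_assembly(seqs)
}

#' Write a genome assembly to FASTA
#'
#' @param assembly a \code{GenomeAssembly}.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(assembly, path, width = 70L) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in assembly$chrom_names) {
    s <- assembly$chrom_seqs[[nm]]
    writeLines(paste0(">", nm), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Fetch the sequence of an interval
#'
#' Minus-strand intervals are returned reverse-complemented.
#'
#' @param assembly a \code{GenomeAssembly}.
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end exclusive end.
#' @param strand \code{"+"} or \code{"-"}.
#' @return a character scalar of length \code{end - start}.
#' @export
get_sequence <- function(assembly, chrom, start, end, strand = "+") {
  len <- assembly$chrom_lengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > len || start >= end)
    stop(sprintf("invalid interval %s:[%d,%d) on a %d-base chromosome",
                 chrom, start, end, len))
  s <- substr(assembly$chrom_seqs[[chrom]], start + 1L, end)
  if (strand == "-") s <- reverse_complement(s)
  s
}

# ---- Intervals --------------------------------------------------------------

#' Construct genomic intervals (0-based, half-open)
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive starts.
#' @param end exclusive ends.
#' @param strand strands, \code{"+"} or \code{"-"}; recycled.
#' @return a data.frame with columns \code{chrom, start, end, strand}.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "+") {
  if (any(start < 0) || any(start >= end))
    stop("intervals require 0 <= start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end),
             strand = rep_len(as.character(strand), length(chrom)),
             stringsAsFactors = FALSE)
}

#' Read intervals from a BED file (BED3 or BED6)
#'
#' Only the first three columns plus, if present, the sixth (strand) are used.
#'
#' @param path path to a tab-separated BED file.
#' @return a data.frame as from \code{\link{genomic_intervals}}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  strand <- if (ncol(df) >= 6) df[[6]] else "+"
  genomic_intervals(df[[1]], df[[2]], df[[3]], strand)
}

#' Write intervals to a BED6 file
#'
#' Rows are written in the given order; name column is the row index and
#' score is 0, so output is deterministic.
#'
#' @param intervals a data.frame with \code{chrom, start, end, strand}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    paste0("w", seq_len(nrow(intervals))), 0L,
                    intervals$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Center a fixed-length window on a bin
#'
#' Each genomic bin (by default 200 bp) is described by a longer neighborhood
#' window (by default 1 kb) with the bin exactly at its center. The window
#' must fit inside the chromosome; no silent clipping is done.
#'
#' @param bin a single-row interval data.frame (the bin).
#' @param window_length window length in bases; the excess over the bin
#'   length must be even.
#' @param chrom_length length of the bin's chromosome, used for bounds
#'   checking (optional; \code{Inf} skips the right-bound check).
#' @return a single-row interval data.frame of length \code{window_length}.
#' @export
window_around_bin <- function(bin, window_length, chrom_length = Inf) {
  bl <- bin$end - bin$start
  if (bl > window_length) stop("bin longer than window")
  flank <- (window_length - bl) / 2
  if (flank != floor(flank))
    stop("window_length minus bin length must be even")
  start <- bin$start - flank
  end <- bin$end + flank
  if (start < 0 || end > chrom_length)
    stop(sprintf("window [%d,%d) overruns chromosome of length %s",
                 start, end, format(chrom_length)))
  genomic_intervals(bin$chrom, start, end, bin$strand)
}

# ---- Sequence encoding ------------------------------------------------------

BASES <- c("A", "C", "G", "T")

#' One-hot encode a DNA sequence
#'
#' @param sequence character scalar over \code{A,C,G,T,N}.
#' @return a 4 x L numeric matrix with rows \code{A,C,G,T}; an \code{N}
#'   yields an all-zero column.
#' @export
one_hot <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, BASES)
  m <- matrix(0, nrow = 4L, ncol = length(chars),
              dimnames = list(BASES, NULL))
  keep <- !is.na(idx)
  m[cbind(idx[keep], which(keep))] <- 1
  m
}

#' Reverse complement a DNA sequence
#'
#' @param sequence character scalar over \code{A,C,G,T,N}.
#' @return the Watson-Crick complement, reversed; \code{N} maps to \code{N}.
#' @export
reverse_complement <- function(sequence) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(sequence, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Build the one-hot window for an interval
#'
#' @param assembly a \code{GenomeAssembly}.
#' @param interval single-row interval data.frame.
#' @return a list with \code{interval}, \code{sequence} and \code{onehot}
#'   (4 x L), class \code{SequenceWindow}.
#' @export
sequence_window <- function(assembly, interval) {
  s <- get_sequence(assembly, interval$chrom, interval$start, interval$end,
                    interval$strand)
  structure(list(interval = interval, sequence = s, onehot = one_hot(s)),
            class = "SequenceWindow")
}

# ---- Variants ---------------------------------------------------------------

#' Read a minimal 5-column VCF-like file
#'
#' Only \code{CHROM, POS, ID, REF, ALT} are used; header lines beginning with
#' \code{#} are skipped. Positions are 1-based as in VCF and converted to
#' 0-based internally downstream.
#'
#' @param path path to the file.
#' @return a data.frame with columns \code{chrom, pos, id, ref, alt}.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(f, length, integer(1))
  if (any(n < 5)) stop("VCF line with fewer than 5 columns at record ",
                       which(n < 5)[1])
  data.frame(chrom = vapply(f, `[[`, "", 1),
             pos = as.integer(vapply(f, `[[`, "", 2)),
             id = vapply(f, `[[`, "", 3),
             ref = toupper(vapply(f, `[[`, "", 4)),
             alt = toupper(vapply(f, `[[`, "", 5)),
             stringsAsFactors = FALSE)
}

#' Validate a variant against an assembly
#'
#' @param assembly a \code{GenomeAssembly}.
#' @param variant a single-row data.frame with \code{chrom, pos} (1-based),
#'   \code{ref, alt}.
#' @return \code{TRUE} invisibly, or an error describing the mismatch.
#' @export
validate_variant <- function(assembly, variant) {
  if (variant$ref == variant$alt) stop("variant ref and alt are identical")
  pos0 <- variant$pos - 1L
  found <- substr(assembly$chrom_seqs[[variant$chrom]], pos0 + 1L,
                  pos0 + nchar(variant$ref))
  if (!identical(found, variant$ref))
    stop(sprintf("variant ref mismatch at %s:%d: expected '%s', found '%s'",
                 variant$chrom, variant$pos, variant$ref, found))
  invisible(TRUE)
}

#' Build reference and alternate windows for a variant
#'
#' Both windows have exactly \code{window_length} bases and are centered on
#' the variant's first reference base. For indels the edited chromosome is
#' re-windowed around the same anchor, so downstream bases shift in or out at
#' the right edge while the window length is preserved.
#'
#' @param assembly a \code{GenomeAssembly}.
#' @param variant single-row data.frame with \code{chrom, pos} (1-based),
#'   \code{ref, alt}.
#' @param window_length window length in bases (even).
#' @return a list with character fields \code{ref_window} and
#'   \code{alt_window} plus the anchor interval.
#' @export
apply_variant <- function(assembly, variant, window_length = 1000L) {
  validate_variant(assembly, variant)
  pos0 <- variant$pos - 1L          # 0-based index of first ref base
  chrom_seq <- assembly$chrom_seqs[[variant$chrom]]
  clen <- nchar(chrom_seq)
  left <- floor(window_length / 2)
  start <- pos0 - left
  end <- start + window_length
  if (start < 0 || end > clen)
    stop(sprintf("variant window [%d,%d) overruns chromosome %s (%d bases)",
                 start, end, variant$chrom, clen))
  ref_window <- substr(chrom_seq, start + 1L, end)
  # edit the chromosome, then re-window at the same anchor
  edited <- paste0(substr(chrom_seq, 1L, pos0),
                   variant$alt,
                   substr(chrom_seq, pos0 + nchar(variant$ref) + 1L, clen))
  if (end > nchar(edited))
    stop("variant window would overrun the edited chromosome end")
  alt_window <- substr(edited, start + 1L, end)
  list(ref_window = ref_window, alt_window = alt_window,
       interval = genomic_intervals(variant$chrom, start, end, "+"))
}
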