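#' Random DNA sequence
#'
#' Uniform i.i.d. bases; used throughout the synthetic-genome generator.
#'
#' @param n Sequence length in bp.
#' @param gc GC content (probability of G or C per base).
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n, gc = 0.45) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Percentage of a count over a total
#'
#' The accounting helper used by all summary reports: `100 * count / total`,
#' rounded to a fixed number of decimal places. Keeping rounding in one place
#' makes report percentages reproducible from printed counts.
#'
#' @param count Numerator count(s).
#' @param total Denominator total.
#' @param digits Decimal places to round to (default 2).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' pct(12891, 73594, digits = 1)
pct <- function(count, total, digits = 2) {
  if (any(total <= 0)) stop("total must be positive")
  round(100 * count / total, digits)
}

#' Assembly N50
#'
#' The length L such that sequences of length >= L together contain at least
#' half the total assembled bases.
#'
#' @param lengths Integer vector of sequence lengths.
#' @return The N50 length.
#' @export
#' @examples
#' assembly_n50(c(100, 200, 300, 400))
assembly_n50 <- function(lengths) {
  if (length(lengths) == 0) return(0L)
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  csum <- cumsum(lengths)
  lengths[which(csum >= sum(lengths) / 2)[1]]
}

# Coerce character vector / DNAStringSet to a named character vector.
as_seq_character <- function(x, what = "sequences") {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop(what, " must be a character vector or DNAStringSet")
  if (is.null(names(x)) && length(x)) names(x) <- paste0("seq", seq_along(x))
  x
}

#' Split chromosomes into scaffold-like pieces
#'
#' Cuts each sequence at the supplied breakpoints (or into `n_pieces` equal
#' parts), producing a scaffold set with deterministic ids
#' `<chrom>_s<index>`. Useful for turning simulated chromosomes into a
#' scaffold assembly for anchoring and filtering exercises.
#'
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param n_pieces Number of equal pieces per chromosome.
#' @param breaks Optional named list mapping chromosome name to a vector of
#'   internal 1-based break positions (a piece ends just before each break).
#'   Overrides `n_pieces`.
#' @return Named character vector of scaffold sequences.
#' @export
split_chromosomes <- function(genome, n_pieces = 4, breaks = NULL) {
  genome <- as_seq_character(genome, "genome")
  out <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    len <- nchar(s)
    if (!is.null(breaks) && !is.null(breaks[[chrom]])) {
      bp <- sort(unique(breaks[[chrom]]))
      bp <- bp[bp > 1 & bp <= len]
    } else {
      bp <- floor(seq(1, len + 1, length.out = n_pieces + 1))
      bp <- bp[-c(1, length(bp))]
    }
    starts <- c(1, bp)
    ends <- c(bp - 1, len)
    pieces <- substring(s, starts, ends)
    names(pieces) <- sprintf("%s_s%02d", chrom, seq_along(pieces))
    out[[chrom]] <- pieces
  }
  unlist(unname(out))
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) {
    seqs <- Biostrings::DNAStringSet(as_seq_character(seqs))
  }
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
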