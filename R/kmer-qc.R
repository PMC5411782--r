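#' Count canonical k-mers
#'
#' Counts every k-length word of the input sequences after canonicalisation:
#' a k-mer and its reverse complement are collapsed onto the
#' lexicographically smaller of the two, the convention used by k-mer
#' analysis toolkits. Windows containing non-ACGT symbols are skipped. Odd k
#' is required so that no k-mer can equal its own reverse complement.
#'
#' @param sequences Character vector or `DNAStringSet`.
#' @param k Word length in bp; must be odd and at most 63. Spectra analyses
#'   conventionally use `k = 31`.
#' @return A tibble with columns `kmer` (canonical k-mer) and `count`,
#'   sorted by `kmer`.
#' @export
#' @examples
#' count_kmers(c("ACGTA"), k = 3)
count_kmers <- function(sequences, k = 31) {
  check_k(k)
  sequences <- as_seq_character(sequences)
  if (length(sequences) == 0) stop("sequences must be non-empty")
  res <- cpp_kmer_counts(sequences, as.integer(k))
  tibble(kmer = res$kmer, count = as.integer(res$count)) %>%
    arrange(.data$kmer)
}

check_k <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k > 63) {
    stop("k must be a single value between 1 and 63")
  }
  if (k %% 2 == 0) {
    stop("k must be odd: an even k-mer can be its own reverse complement, ",
         "making canonical counting ambiguous")
  }
  invisible(k)
}

#' k-mer multiplicity spectrum
#'
#' Histogram of distinct canonical k-mers by their multiplicity (number of
#' occurrences) in a sequence set, the x/y axes of a k-mer spectrum plot.
#'
#' @inheritParams count_kmers
#' @return An object of class `kmer_spectrum`: a list with `k` and `hist`,
#'   a tibble of `multiplicity` and `n_kmers` (zero-count multiplicities
#'   omitted).
#' @export
kmer_spectrum <- function(sequences, k = 31) {
  check_k(k)
  sequences <- as_seq_character(sequences)
  if (length(sequences) == 0) stop("sequences must be non-empty")
  h <- cpp_kmer_hist(sequences, as.integer(k))
  out <- list(
    k = as.integer(k),
    hist = tibble(multiplicity = seq_along(h), n_kmers = as.numeric(h)) %>%
      filter(.data$n_kmers > 0)
  )
  class(out) <- "kmer_spectrum"
  out
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("k-mer spectrum (k = %d): %g distinct k-mers, multiplicity 1..%d\n",
              x$k, sum(x$hist$n_kmers), max(x$hist$multiplicity)))
  invisible(x)
}

# Dense multiplicity histogram (1..max) from a kmer_spectrum.
dense_hist <- function(spectrum) {
  if (nrow(spectrum$hist) == 0) return(numeric(0))
  m_max <- max(spectrum$hist$multiplicity)
  h <- numeric(m_max)
  h[spectrum$hist$multiplicity] <- spectrum$hist$n_kmers
  h
}

#' Decompose a read k-mer spectrum by assembly copy number
#'
#' The spectra-cn analysis: every distinct canonical k-mer of the read set
#' is binned jointly by its multiplicity in the reads (rows) and its copy
#' number in the assembly (columns 0, 1, 2, ..., with the last column
#' aggregating copy numbers above `c_max`). Row 0 holds assembly k-mers
#' never seen in the reads (artifact content); column 0 above row 0 holds
#' read k-mers absent from the assembly (missing content).
#'
#' @param reads Read sequences (character vector or `DNAStringSet`).
#' @param assembly Assembly sequences.
#' @param k Word length; must be odd, and identical for both inputs.
#' @param c_max Highest copy number given its own column; larger copy
#'   numbers land in the open-ended final column.
#' @return An object of class `spectra_cn`: list with `k`, `c_max` and
#'   `matrix` (rows named `m0`, `m1`, ...; columns `c0`..`c<c_max>`,
#'   `c>c_max`).
#' @export
spectra_cn <- function(reads, assembly, k = 31, c_max = 10) {
  check_k(k)
  if (c_max < 1) stop("c_max must be >= 1")
  reads <- as_seq_character(reads, "reads")
  assembly <- as_seq_character(assembly, "assembly")
  if (length(reads) == 0 || length(assembly) == 0) {
    stop("reads and assembly must be non-empty")
  }
  m <- cpp_spectra_cn(reads, assembly, as.integer(k), as.integer(c_max))
  rownames(m) <- paste0("m", seq_len(nrow(m)) - 1)
  colnames(m) <- c(paste0("c", 0:c_max), paste0("c>", c_max))
  out <- list(k = as.integer(k), c_max = as.integer(c_max), matrix = m)
  class(out) <- "spectra_cn"
  out
}

#' @export
print.spectra_cn <- function(x, ...) {
  cat(sprintf("spectra-cn (k = %d): %d multiplicity rows x %d copy-number columns\n",
              x$k, nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  artifact k-mers (assembly-only): %g\n", sum(x$matrix[1, -1])))
  invisible(x)
}

# Read-spectrum histogram implied by a spectra_cn (row sums above row 0);
# used for conservation checks and threshold detection.
spectra_read_hist <- function(sc) {
  stopifnot(inherits(sc, "spectra_cn"))
  if (nrow(sc$matrix) < 2) return(numeric(0))
  rowSums(sc$matrix)[-1]
}

#' Detect the error/content multiplicity threshold of a read spectrum
#'
#' Sequencing errors produce a peak of low-multiplicity k-mers to the left
#' of the main coverage peak. The threshold separating them is taken as the
#' multiplicity at the first local minimum of the histogram after smoothing
#' with a centred 3-point moving average: the histogram must descend from
#' an error peak at multiplicity 1 and the valley is the point where it
#' first turns upward again. If the smoothed histogram starts by rising
#' (no error peak, as with error-free reads) or never turns upward (a
#' monotone histogram), the configured default floor is returned with a
#' warning.
#'
#' @param spectrum A `kmer_spectrum`, or a numeric multiplicity histogram
#'   (element i = number of distinct k-mers with multiplicity i).
#' @param default Fallback threshold when no valley exists (default 2).
#' @return A single integer multiplicity.
#' @export
error_threshold <- function(spectrum, default = 2) {
  h <- if (inherits(spectrum, "kmer_spectrum")) dense_hist(spectrum) else as.numeric(spectrum)
  n <- length(h)
  if (n >= 3) {
    sm <- h
    sm[2:(n - 1)] <- (h[1:(n - 2)] + h[2:(n - 1)] + h[3:n]) / 3
    if (sm[2] < sm[1]) {
      for (m in 2:(n - 1)) {
        if (sm[m + 1] > sm[m]) return(as.integer(m))
      }
    }
  }
  warning("no local minimum found in k-mer spectrum; using default threshold ",
          default)
  as.integer(default)
}

#' Summarise assembly QC from a spectra-cn decomposition
#'
#' Reports the three headline diagnostics of a spectra-cn plot:
#' * `missing_kmers`: read k-mers at or above the error threshold that are
#'   absent from the assembly (column 0) - genuine content not assembled;
#' * `artifact_kmers`: assembly k-mers with read multiplicity zero -
#'   chimeric joins or consensus errors;
#' * `duplicated_kmers`: k-mers in the single-copy multiplicity band that
#'   appear at copy number >= 2 in the assembly - artefactual duplication;
#' * `completeness`: 1 - missing / (distinct read k-mers above threshold).
#'
#' @param sc A `spectra_cn` object.
#' @param threshold Error multiplicity threshold; `NULL` (default) detects
#'   it with [error_threshold()].
#' @param single_copy_max Upper multiplicity bound of the single-copy band
#'   used for the duplication count; `NULL` sets it to 1.5x the main-peak
#'   multiplicity.
#' @return An object of class `qc_summary` (also a list) with the fields
#'   above plus `error_threshold` and `single_copy_max`.
#' @export
qc_summary <- function(sc, threshold = NULL, single_copy_max = NULL) {
  stopifnot(inherits(sc, "spectra_cn"))
  hist <- spectra_read_hist(sc)
  if (is.null(threshold)) threshold <- error_threshold(hist)
  if (threshold < 1) stop("threshold must be >= 1")
  m <- sc$matrix
  m_max <- nrow(m) - 1
  artifact <- sum(m[1, -1])
  rows_above <- which(seq_len(m_max) >= threshold) + 1  # matrix rows for m >= threshold
  missing <- if (length(rows_above)) sum(m[rows_above, 1]) else 0
  denom <- if (length(rows_above)) sum(m[rows_above, ]) else 0
  if (denom == 0) {
    warning("no read k-mers at or above the threshold; completeness set to 1")
    completeness <- 1
  } else {
    completeness <- 1 - missing / denom
  }
  if (is.null(single_copy_max)) {
    peak <- if (length(rows_above)) {
      threshold - 1 + which.max(rowSums(m)[rows_above])
    } else m_max
    single_copy_max <- max(threshold, floor(1.5 * peak))
  }
  band <- which(seq_len(m_max) >= threshold & seq_len(m_max) <= single_copy_max) + 1
  duplicated <- if (length(band)) sum(m[band, -(1:2), drop = FALSE]) else 0
  out <- list(
    error_threshold = as.integer(threshold),
    single_copy_max = as.integer(single_copy_max),
    missing_kmers = missing,
    artifact_kmers = artifact,
    duplicated_kmers = duplicated,
    completeness = completeness
  )
  class(out) <- "qc_summary"
  out
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("k-mer QC summary\n")
  cat(sprintf("  error threshold      : %d\n", x$error_threshold))
  cat(sprintf("  missing k-mers       : %g\n", x$missing_kmers))
  cat(sprintf("  artifact k-mers      : %g\n", x$artifact_kmers))
  cat(sprintf("  duplicated k-mers    : %g\n", x$duplicated_kmers))
  cat(sprintf("  completeness         : %.4f\n", x$completeness))
  invisible(x)
}

#' Write a spectra-cn matrix to TSV
#' @param sc A `spectra_cn` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_cn <- function(sc, path) {
  stopifnot(inherits(sc, "spectra_cn"))
  df <- data.frame(multiplicity = seq_len(nrow(sc$matrix)) - 1, sc$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stacked spectra-cn histogram plot
#'
#' Mirrors the conventional colour semantics of spectra-cn plots: content
#' absent from the assembly in black, single-copy in red, two-copy in
#' green, and so on.
#'
#' @param sc A `spectra_cn` object.
#' @param max_multiplicity Truncate the x-axis at this multiplicity.
#' @return A ggplot object.
#' @export
plot_spectra_cn <- function(sc, max_multiplicity = NULL) {
  stopifnot(inherits(sc, "spectra_cn"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- as.data.frame(sc$matrix)
  df$multiplicity <- seq_len(nrow(df)) - 1
  long <- pivot_longer(df, -"multiplicity", names_to = "copy", values_to = "n")
  long <- filter(long, .data$multiplicity > 0)
  if (!is.null(max_multiplicity)) {
    long <- filter(long, .data$multiplicity <= max_multiplicity)
  }
  long$copy <- factor(long$copy, levels = colnames(sc$matrix))
  cols <- c("black", "red", "forestgreen", "purple", "orange", "blue",
            "brown", "pink", "cyan", "darkgreen", "grey50", "grey80")
  cols <- rep(cols, length.out = nlevels(long$copy))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$multiplicity, y = .data$n,
                                     fill = .data$copy)) +
    ggplot2::geom_col(position = "stack", width = 1) +
    ggplot2::scale_fill_manual(values = cols, name = "assembly copies") +
    ggplot2::labs(x = "k-mer multiplicity in reads",
                  y = "distinct k-mers") +
    ggplot2::theme_minimal()
}
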