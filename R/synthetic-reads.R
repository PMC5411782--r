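#' Simulate shotgun reads from a genome
#'
#' Draws single-end reads uniformly from both strands of the genome to the
#' requested fold coverage. Sequencing noise is substitution-only at a
#' uniform per-base rate (the replacement base always differs from the
#' original). Each read name encodes its source coordinates
#' (`read<N>|<chromosome>|<start>|<strand>`) so error rates and coverage
#' can be audited without alignment.
#'
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences, or a `synthetic_genome`.
#' @param coverage Fold coverage (> 0).
#' @param read_len Read length in bp; must not exceed the shortest
#'   chromosome.
#' @param error_rate Per-base substitution probability in \[0, 0.1).
#' @param tile If `TRUE`, part of the read budget is spent on a
#'   deterministic tiling (step `read_len %/% 2`, plus a read flush with
#'   each chromosome end) so that every position - and hence every k-mer
#'   up to half the read length - is covered by at least one read; the
#'   remainder is sampled randomly as usual. Purely random sampling leaves
#'   chromosome-end k-mers uncovered with appreciable probability, which
#'   is indistinguishable from missing content in a spectra analysis.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @return Named character vector of read sequences. The read count is
#'   `round(coverage * genome_length / read_len)`, so total read bases
#'   match the requested coverage to within one read.
#' @export
generate_reads <- function(genome, coverage = 30, read_len = 250,
                           error_rate = 0, tile = FALSE, seed = 1) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$genome
  genome <- as_seq_character(genome, "genome")
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate >= 0.1) stop("error_rate must be in [0, 0.1)")
  lens <- nchar(genome)
  if (read_len > min(lens)) {
    stop("read_len (", read_len, ") exceeds the shortest chromosome (",
         min(lens), " bp)")
  }
  set.seed(seed)
  g_len <- sum(as.numeric(lens))
  n_reads <- round(coverage * g_len / read_len)
  n_start <- lens - read_len + 1L
  tile_chrom <- integer(0)
  tile_start <- integer(0)
  if (tile) {
    step <- max(1L, read_len %/% 2L)
    for (ci in seq_along(genome)) {
      st <- unique(c(seq(1L, n_start[ci], by = step), n_start[ci]))
      tile_chrom <- c(tile_chrom, rep(ci, length(st)))
      tile_start <- c(tile_start, st)
    }
    if (length(tile_start) > n_reads) {
      stop("coverage too low to accommodate the tiling reads; increase coverage")
    }
  }
  n_rand <- n_reads - length(tile_start)
  chrom_idx <- c(tile_chrom,
                 sample.int(length(genome), n_rand, replace = TRUE,
                            prob = n_start))
  starts <- c(tile_start, floor(runif(n_rand) * n_start[chrom_idx[
    seq(length(tile_start) + 1L, length.out = n_rand)]]) + 1L)
  strands <- c(rep("+", length(tile_start)),
               sample(c("+", "-"), n_rand, replace = TRUE))
  reads <- character(n_reads)
  for (ci in seq_along(genome)) {
    sel <- chrom_idx == ci
    if (!any(sel)) next
    reads[sel] <- substring(genome[[ci]], starts[sel],
                            starts[sel] + read_len - 1L)
  }
  rc <- strands == "-"
  if (any(rc)) reads[rc] <- revcomp(reads[rc])
  if (error_rate > 0) {
    n_err <- rbinom(n_reads, read_len, error_rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(n_err > 0)) {
      p <- sample.int(read_len, n_err[i])
      ch <- strsplit(reads[i], "")[[1]]
      for (j in p) ch[j] <- sample(setdiff(bases, ch[j]), 1)
      reads[i] <- paste(ch, collapse = "")
    }
  }
  names(reads) <- sprintf("read%07d|%s|%d|%s", seq_len(n_reads),
                          names(genome)[chrom_idx], starts, strands)
  reads
}
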