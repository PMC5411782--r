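# Brute-force oracles, independent of the package's C++ counting path.

# canonical k-mer counts by direct substring enumeration
oracle_kmer_counts <- function(seqs, k) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  out <- list()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      key <- min(w, rc(w))
      out[[key]] <- (out[[key]] %||% 0) + 1
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full spectra-cn matrix from the dictionary oracle
oracle_spectra_matrix <- function(reads, assembly, k, c_max) {
  rm <- oracle_kmer_counts(reads, k)
  am <- oracle_kmer_counts(assembly, k)
  m_max <- max(0, unlist(rm))
  mat <- matrix(0, nrow = m_max + 1, ncol = c_max + 2)
  for (key in names(rm)) {
    cc <- min(am[[key]] %||% 0, c_max + 1)
    mat[rm[[key]] + 1, cc + 1] <- mat[rm[[key]] + 1, cc + 1] + 1
  }
  for (key in setdiff(names(am), names(rm))) {
    cc <- min(am[[key]], c_max + 1)
    mat[1, cc + 1] <- mat[1, cc + 1] + 1
  }
  mat
}

oracle_distinct_kmers <- function(seqs, k) names(oracle_kmer_counts(seqs, k))

# shared small synthetic genome, built once per test run
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_genome(genome_config(
        n_triads = 28, seed = 11, intergenic_length = 600,
        repeat_fraction = 0.10))
    }
    cache
  }
})

# random DNA helper for fixtures (independent of package internals)
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
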