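test_that("canonical k-mer counting matches the brute-force oracle", {
  cases <- list(
    list(seqs = "ACGTA", k = 3),
    list(seqs = "AAAA", k = 3),
    list(seqs = c("ACGTACGTAGCTTTAGC", "GGGCCCATATAT"), k = 5),
    list(seqs = rand_seq(400, seed = 5), k = 21),
    list(seqs = c(rand_seq(150, seed = 6), rand_seq(90)), k = 31),
    list(seqs = "ACGTNACGT", k = 3)  # windows with N skipped
  )
  for (cs in cases) {
    got <- count_kmers(cs$seqs, k = cs$k)
    want <- oracle_kmer_counts(cs$seqs, cs$k)
    expect_setequal(got$kmer, names(want))
    expect_equal(got$count[match(names(want), got$kmer)],
                 as.integer(unlist(want)), ignore_attr = TRUE)
  }
})

test_that("k-mer counting edge cases behave as specified", {
  # palindromic-symmetric homopolymer collapses onto the canonical AAA
  expect_equal(count_kmers("AAAA", k = 3),
               tibble::tibble(kmer = "AAA", count = 2L))
  # sequence shorter than k yields an empty table
  expect_equal(nrow(count_kmers("ACG", k = 5)), 0)
  # even k is ambiguous under canonicalisation
  expect_error(count_kmers("ACGTACGT", k = 4), "odd")
  # no input sequences at all is an error
  expect_error(count_kmers(character(0), k = 3), "non-empty")
})

test_that("reverse-complemented sequences give identical spectra", {
  s <- rand_seq(300, seed = 9)
  a <- count_kmers(s, k = 7)
  b <- count_kmers(polyqc::revcomp(s), k = 7)
  expect_equal(a, b)
})

test_that("spectra-cn equals the dictionary oracle entry for entry", {
  set.seed(42)
  genome <- c(chr1 = rand_seq(4000), chr2 = rand_seq(2500))
  reads <- generate_reads(genome, coverage = 8, read_len = 120, seed = 3)
  for (k in c(15, 31)) {
    sc <- spectra_cn(reads, genome, k = k, c_max = 4)
    want <- oracle_spectra_matrix(unname(reads), unname(genome), k, 4)
    expect_equal(unname(sc$matrix), want)
  }
})

test_that("spectra-cn conserves rows against the read spectrum and columns against the assembly", {
  genome <- c(chr1 = rand_seq(3000, seed = 21), chr2 = rand_seq(1500))
  reads <- generate_reads(genome, coverage = 6, read_len = 100,
                          error_rate = 0.01, seed = 4)
  k <- 17
  sc <- spectra_cn(reads, genome, k = k, c_max = 6)
  read_hist <- kmer_spectrum(reads, k = k)$hist
  # row conservation: row sums above m=0 reproduce the read histogram
  rows <- rowSums(sc$matrix)[-1]
  expect_equal(unname(rows[rows > 0]),
               read_hist$n_kmers[match(which(rows > 0), read_hist$multiplicity)])
  # column conservation: k-mers at assembly copy >= 1 total the distinct
  # assembly k-mers
  n_assembly <- nrow(count_kmers(genome, k = k))
  expect_equal(sum(sc$matrix[, -1]), n_assembly)
})

test_that("an assembly identical to the read source has no missing or artifact content", {
  sim <- shared_sim()
  genome <- sim$genome[1:3]
  reads <- generate_reads(genome, coverage = 40, read_len = 150, seed = 7,
                          tile = TRUE)
  sc <- spectra_cn(reads, genome, k = 31, c_max = 8)
  # artifact row: no assembly-only k-mers
  expect_equal(sum(sc$matrix[1, -1]), 0)
  qs <- qc_summary(sc, threshold = 3)
  expect_equal(qs$artifact_kmers, 0)
  expect_equal(qs$missing_kmers, 0)
  expect_equal(qs$completeness, 1)
})

test_that("deleting a chromosome surfaces exactly its private k-mers as missing", {
  genome <- c(chr1 = rand_seq(5000, seed = 31), chr2 = rand_seq(3000),
              chr3 = rand_seq(2000))
  reads <- generate_reads(genome, coverage = 25, read_len = 100, seed = 8)
  partial <- genome[c("chr1", "chr2")]
  k <- 21
  sc <- spectra_cn(reads, partial, k = k, c_max = 5)
  qs <- qc_summary(sc, threshold = 2)
  private <- setdiff(oracle_distinct_kmers(genome["chr3"], k),
                     oracle_distinct_kmers(partial, k))
  # every private chr3 k-mer well covered by reads shows up in column 0;
  # low-multiplicity stragglers below the threshold are excluded on both sides
  read_counts <- oracle_kmer_counts(unname(reads), k)
  private_above <- sum(vapply(private, function(x)
    (read_counts[[x]] %||% 0) >= 2, TRUE))
  expect_equal(qs$missing_kmers, private_above)
})

test_that("duplicating a chromosome moves its unique k-mers from copy 1 to copy 2", {
  genome <- c(chr1 = rand_seq(4000, seed = 41), chr2 = rand_seq(3000))
  reads <- generate_reads(genome, coverage = 20, read_len = 100, seed = 9)
  k <- 21
  dup <- c(genome, chr1b = unname(genome[["chr1"]]))
  sc1 <- spectra_cn(reads, genome, k = k, c_max = 5)
  sc2 <- spectra_cn(reads, dup, k = k, c_max = 5)
  only1 <- setdiff(oracle_distinct_kmers(genome["chr1"], k),
                   oracle_distinct_kmers(genome["chr2"], k))
  shift <- length(only1)
  expect_equal(sum(sc2$matrix[, 2]), sum(sc1$matrix[, 2]) - shift)
  expect_equal(sum(sc2$matrix[, 3]), sum(sc1$matrix[, 3]) + shift)
})

test_that("error threshold finds the valley of a bimodal spectrum", {
  # mixture: error peak decaying steeply from m=1, main coverage peak at
  # m=30, valley placed at m=12
  hist <- c(seq(4000, 100, length.out = 12),        # m = 1..12: error tail
            seq(500, 2000, length.out = 18),        # m = 13..30: rise to peak
            seq(1900, 50, length.out = 30))         # m = 31..60: decay
  expect_equal(which.min(hist[1:30]), 12)  # fixture sanity
  expect_equal(error_threshold(hist), 12L)
})

test_that("spectra without a valley fall back to the default threshold with a warning", {
  expect_warning(t1 <- error_threshold(1000 * exp(-0.3 * (1:40))),
                 "default")
  expect_equal(t1, 2L)
  # error-free unimodal spectrum: a coverage peak but no error peak, so
  # the histogram starts by rising
  unimodal <- stats::dpois(1:60, lambda = 30) * 1e6
  expect_warning(t2 <- error_threshold(unimodal), "default")
  expect_equal(t2, 2L)
  # override the fallback floor
  expect_warning(t3 <- error_threshold(unimodal, default = 5), "default")
  expect_equal(t3, 5L)
})

test_that("artifact content from an inserted chimera is quantified by the set oracle", {
  genome <- c(chr1 = rand_seq(6000, seed = 51), chr2 = rand_seq(4000))
  reads <- generate_reads(genome, coverage = 25, read_len = 100, seed = 11)
  k <- 21
  chimera <- rand_seq(1000)
  assembly <- c(genome, chimX = chimera)
  sc <- spectra_cn(reads, assembly, k = k, c_max = 5)
  qs <- qc_summary(sc, threshold = 2)
  # exact value: assembly k-mers never seen in a read
  want_exact <- length(setdiff(oracle_distinct_kmers(assembly, k),
                               oracle_distinct_kmers(unname(reads), k)))
  expect_equal(qs$artifact_kmers, want_exact)
  # and the chimera's private k-mers account for (almost) all of it; the
  # remainder is the handful of chromosome-end k-mers random reads miss
  chim_private <- length(setdiff(oracle_distinct_kmers(chimera, k),
                                 oracle_distinct_kmers(genome, k)))
  expect_gte(qs$artifact_kmers, chim_private)
  expect_lte(qs$artifact_kmers - chim_private, 40)
})

test_that("an empty completeness denominator is guarded", {
  genome <- c(chr1 = rand_seq(2000, seed = 61))
  reads <- generate_reads(genome, coverage = 5, read_len = 100, seed = 12)
  sc <- spectra_cn(reads, genome, k = 15, c_max = 3)
  expect_warning(qs <- qc_summary(sc, threshold = nrow(sc$matrix) + 10),
                 "completeness")
  expect_equal(qs$completeness, 1)
})

test_that("assembly edits move content monotonically", {
  genome <- c(chr1 = rand_seq(3000, seed = 71), chr2 = rand_seq(2000),
              chr3 = rand_seq(1500))
  reads <- generate_reads(genome, coverage = 20, read_len = 100, seed = 13)
  k <- 21
  qc_of <- function(assembly) {
    qc_summary(spectra_cn(reads, assembly, k = k, c_max = 5), threshold = 2)
  }
  full <- qc_of(genome)
  # progressively deleting assembly sequence never decreases missing content
  drop1 <- qc_of(genome[c("chr1", "chr2")])
  drop2 <- qc_of(genome["chr1"])
  expect_true(drop1$missing_kmers >= full$missing_kmers)
  expect_true(drop2$missing_kmers >= drop1$missing_kmers)
  # adding novel sequence never decreases artifact content
  plus <- qc_of(c(genome, extra = rand_seq(800)))
  expect_true(plus$artifact_kmers >= full$artifact_kmers)
})
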