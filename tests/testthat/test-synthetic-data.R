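small_cfg <- function(...) {
  args <- utils::modifyList(list(n_triads = 14, intergenic_length = 400,
                                 repeat_fraction = 0.05, seed = 77),
                            list(...))
  do.call(genome_config, args)
}

test_that("configuration errors name the offending field", {
  expect_error(genome_config(n_triads = 0), "n_triads")
  expect_error(genome_config(homoeolog_divergence = 0.5), "homoeolog_divergence")
  expect_error(genome_config(repeat_fraction = 0.95), "repeat_fraction")
  expect_error(genome_config(tsd_length = -1), "tsd_length")
})

test_that("zero divergence gives three identical copies of every gene", {
  sim <- generate_genome(small_cfg(homoeolog_divergence = 0))
  mem <- sim$truth$members
  for (tid in unique(mem$triad_id)) {
    m <- mem[mem$triad_id == tid, ]
    seqs <- mapply(function(chr, s, e) substr(sim$genome[[chr]], s, e),
                   m$chromosome, m$start, m$end)
    expect_equal(length(unique(seqs)), 1)
  }
})

test_that("genome generation is byte-identical under a fixed seed", {
  s1 <- generate_genome(small_cfg())
  s2 <- generate_genome(small_cfg())
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$gene_models, s2$gene_models)
  f1 <- tempfile(fileext = ".gff3")
  f2 <- tempfile(fileext = ".gff3")
  write_gff3(s1$gene_models, f1)
  write_gff3(s2$gene_models, f2)
  expect_identical(readLines(f1), readLines(f2))
  r1 <- generate_reads(s1, coverage = 3, read_len = 100, seed = 5)
  r2 <- generate_reads(s2, coverage = 3, read_len = 100, seed = 5)
  expect_identical(r1, r2)
})

test_that("every triad has one member per subgenome, minus planted deletions", {
  sim <- generate_genome(small_cfg())
  counts <- table(sim$truth$members$triad_id)
  expect_true(all(counts == 3))
  expect_equal(nrow(sim$truth$triads), 14)
  del <- generate_genome(small_cfg(
    deletions = data.frame(triad_id = "t003", subgenome = "D")))
  m3 <- del$truth$members[del$truth$members$triad_id == "t003", ]
  expect_setequal(m3$subgenome, c("A", "B"))
})

test_that("per-gene substitution counts follow the binomial model", {
  div <- 0.05
  sim <- generate_genome(small_cfg(homoeolog_divergence = div, seed = 2))
  mem <- sim$truth$members
  anc <- setNames(sim$truth$ancestors$seq, sim$truth$ancestors$triad_id)
  mism <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  subs <- lens <- numeric(nrow(mem))
  for (i in seq_len(nrow(mem))) {
    m <- mem[i, ]
    a <- substr(sim$genome[[m$chromosome]], m$start, m$end)
    b <- anc[[m$triad_id]]
    expect_equal(nchar(a), nchar(b))
    lens[i] <- nchar(a)
    subs[i] <- mism(a, b)
  }
  expected <- lens * div
  sd3 <- 3 * sqrt(lens * div * (1 - div))
  # a 3-SD band covers 99.7% per gene; tolerate at most one tail event
  # across the 42 gene copies
  expect_lte(sum(abs(subs - expected) > sd3), 1)
  # and in aggregate the rate is right to within 3 SD
  expect_lt(abs(sum(subs) - sum(expected)), 3 * sqrt(sum(lens) * div))
})

test_that("error-free reads are exact genomic substrings at the advertised count", {
  genome <- c(chrA = rand_seq(50000, seed = 501), chrB = rand_seq(50000))
  reads <- generate_reads(genome, coverage = 10, read_len = 100, seed = 6)
  expect_true(abs(length(reads) - 10000) <= 1)
  # audit via source coordinates in the read names
  info <- strsplit(names(reads), "|", fixed = TRUE)
  for (i in sample(length(reads), 200)) {
    src <- substr(genome[[info[[i]][2]]], as.integer(info[[i]][3]),
                  as.integer(info[[i]][3]) + 99)
    if (info[[i]][4] == "-") src <- polyqc::revcomp(src)
    expect_identical(unname(reads[i]), src)
  }
  expect_error(generate_reads(genome, read_len = 60000), "shortest")
  expect_error(generate_reads(genome, coverage = -1), "coverage")
})

test_that("read substitution errors occur at the requested rate", {
  genome <- c(chr = rand_seq(30000, seed = 502))
  rate <- 0.01
  reads <- generate_reads(genome, coverage = 5, read_len = 100,
                          error_rate = rate, seed = 7)
  info <- strsplit(names(reads), "|", fixed = TRUE)
  n_mm <- 0
  n_bases <- 0
  for (i in seq_along(reads)) {
    src <- substr(genome[["chr"]], as.integer(info[[i]][3]),
                  as.integer(info[[i]][3]) + 99)
    if (info[[i]][4] == "-") src <- polyqc::revcomp(src)
    n_mm <- n_mm + sum(strsplit(reads[[i]], "")[[1]] != strsplit(src, "")[[1]])
    n_bases <- n_bases + 100
  }
  expect_lt(abs(n_mm / n_bases - rate), 3 * sqrt(rate * (1 - rate) / n_bases))
})

test_that("the genetic map has the advertised bin structure and honest markers", {
  sim <- shared_sim()
  mp <- suppressMessages(generate_map(sim, bins_per_chromosome = 4,
                                      genic_markers = FALSE, seed = 8))
  # 21 chromosomes x 4 bins
  expect_equal(nrow(unique(mp$map$markers[, c("chromosome", "cM_bin")])), 84)
  expect_equal(nrow(mp$bins), 84)
  # every bin has at least one marker
  expect_true(all(table(paste(mp$map$markers$chromosome,
                              mp$map$markers$cM_bin)) >= 1))
  # without translocations every marker maps to its true chromosome
  expect_equal(mp$map$markers$chromosome[
    match(mp$marker_truth$marker_id, mp$map$markers$marker_id)],
    mp$marker_truth$true_chromosome)
  # markers really occur once: each hits exactly one scaffold position
  hits <- match_markers(mp$marker_seqs, sim$genome)
  expect_equal(nrow(hits), length(mp$marker_seqs))
})

test_that("a planted translocation relocates exactly the recorded block of triads", {
  sim <- shared_sim()
  mp <- suppressMessages(generate_map(
    sim, bins_per_chromosome = 2,
    translocations = data.frame(from_chr = "3D", to_chr = "5A", n_triads = 2),
    seed = 9))
  tt <- mp$translocation_truth
  expect_equal(tt$n_triads, 2L)
  expect_equal(tt$source_chromosome, "5A")
  expect_equal(tt$target_chromosome, "3D")
  moved <- strsplit(tt$triad_ids, ",")[[1]]
  mb <- triad_member_bins(sim, mp)
  # exactly the moved triads have one member whose map chromosome differs
  # from its homoeologs' group
  odd <- vapply(split(mb, mb$triad_id), function(df) {
    df <- df[!is.na(df$chromosome), ]
    length(unique(sub("[A-Z]$", "", df$chromosome))) > 1
  }, TRUE)
  expect_setequal(names(odd)[odd], moved)
})

test_that("expression simulation is deterministic and label-complete", {
  triads <- shared_sim()$truth$triads
  e1 <- generate_expression(triads, seed = 10)
  e2 <- generate_expression(triads, seed = 10)
  expect_identical(e1$counts, e2$counts)
  # one pattern label per triad per stress condition
  expect_equal(nrow(e1$labels$patterns), nrow(triads) * 2)
  expect_equal(nrow(e1$labels$balance), nrow(triads))
  expect_warning(generate_expression(triads, n_reps = 1, seed = 1),
                 "replicates")
})

test_that("noise-free flat expression classifies as fully balanced and non-DE", {
  triads <- shared_sim()$truth$triads
  ex <- generate_expression(triads, pattern_mix = c(flat = 1),
                            imbalance_fraction = 0, dispersion = 0, seed = 11)
  tpm <- tpm_normalize(ex$counts, ex$gene_lengths)
  bal <- classify_balance(tpm, triads, ex$samples)
  expect_equal(bal$n_unbalanced, 0)
  expect_equal(bal$n_expressed, nrow(triads))
  st <- classify_stress(tpm, triads, ex$samples)
  expect_true(all(st$pattern == "not-DE"))
})

test_that("a pure single-homoeolog mix is recovered at zero dispersion", {
  triads <- shared_sim()$truth$triads
  ex <- generate_expression(triads, pattern_mix = c("1-DE" = 1),
                            dispersion = 0, seed = 12)
  tpm <- tpm_normalize(ex$counts, ex$gene_lengths)
  st <- classify_stress(tpm, triads, ex$samples)
  expect_true(all(st$pattern == "1-DE"))
  # and the member-level calls match the planted ones
  truth <- ex$labels$patterns
  joined <- dplyr::inner_join(st, truth, by = c("triad_id", "condition"),
                              suffix = c("", ".t"))
  expect_equal(joined$call_A, joined$call_A.t)
  expect_equal(joined$call_B, joined$call_B.t)
  expect_equal(joined$call_D, joined$call_D.t)
})

test_that("transcript generation realizes exactly the labelled events", {
  sim <- shared_sim()
  # pure intron-retention mix on 20 genes
  g20 <- unique(sim$gene_models$gene_id)[1:20]
  tr <- generate_transcripts(sim$gene_models, as_event_mix = c(IR = 1),
                             genes = g20, seed = 13)
  expect_equal(nrow(tr$labels), 20)
  expect_true(all(tr$labels$event == "IR"))
  for (g in g20) {
    pair <- tr$transcripts[[g]]
    # alternative isoform has one exon fewer: two exons merged over an intron
    expect_equal(nrow(pair[[2]]$exons), nrow(pair[[1]]$exons) - 1)
    expect_equal(classify_as_events(pair)$event, "IR")
  }
  # MXE: the two alternative exons never co-occur in one isoform
  trm <- generate_transcripts(sim$gene_models, as_event_mix = c(MXE = 1),
                              genes = g20[1:5], seed = 14)
  for (g in names(trm$transcripts)) {
    pair <- trm$transcripts[[g]]
    full <- sim$gene_models[sim$gene_models$gene_id == g &
                              sim$gene_models$type == "exon", ]
    mrna <- if (full$strand[[1]] == "+") seq_len(nrow(full)) else rev(seq_len(nrow(full)))
    ex2 <- full[mrna[2], c("start", "end")]
    ex3 <- full[mrna[3], c("start", "end")]
    has <- function(txo, e) any(txo$exons$start == e$start & txo$exons$end == e$end)
    for (txo in pair) {
      expect_false(has(txo, ex2) && has(txo, ex3))
    }
  }
})

test_that("events impossible for a gene's exon count are skipped with a log entry", {
  gm <- tibble::tibble(
    gene_id = "g2x", transcript_id = "g2x.1", seqid = "1A", strand = "+",
    type = "exon", start = c(1, 200), end = c(100, 300),
    phase = NA_integer_)
  expect_message(tr <- generate_transcripts(gm, as_event_mix = c(ES = 1),
                                            seed = 15), "skipped")
  expect_equal(nrow(tr$labels), 0)
  expect_equal(tr$skipped$gene_id, "g2x")
})

test_that("gene models are valid GFF3 with consistent CDS phases", {
  sim <- generate_genome(small_cfg())
  gm <- sim$gene_models
  cds <- gm[gm$type == "CDS", ]
  # total CDS length is a multiple of three for every transcript
  lens <- tapply(cds$end - cds$start + 1, cds$transcript_id, sum)
  expect_true(all(lens %% 3 == 0))
  # phases follow the cumulative-length rule in mRNA order
  for (tid in sample(unique(cds$transcript_id), 10)) {
    seg <- cds[cds$transcript_id == tid, ]
    seg <- seg[order(seg$start, decreasing = seg$strand[[1]] == "-"), ]
    cum <- 0
    for (i in seq_len(nrow(seg))) {
      expect_equal(seg$phase[i], (3 - (cum %% 3)) %% 3)
      cum <- cum + seg$end[i] - seg$start[i] + 1
    }
  }
  f <- tempfile(fileext = ".gff3")
  write_gff3(gm, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  body <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(body) == 9))
  starts <- as.integer(vapply(body, `[[`, "", 4))
  ends <- as.integer(vapply(body, `[[`, "", 5))
  expect_true(all(starts >= 1 & ends >= starts))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(f)
    expect_setequal(as.character(unique(gr$type)),
                    c("gene", "mRNA", "exon", "CDS"))
  }
})

test_that("repeat insertions carry identical flanking target-site duplications", {
  sim <- generate_genome(small_cfg(repeat_fraction = 0.3))
  reps <- sim$truth$repeats
  expect_gt(nrow(reps), 0)
  expect_true(all(nchar(reps$tsd) == 5))
  for (i in seq_len(nrow(reps))) {
    r <- reps[i, ]
    chrom <- sim$genome[[r$chromosome]]
    left <- substr(chrom, r$element_start - 5, r$element_start - 1)
    right <- substr(chrom, r$element_start + r$element_length,
                    r$element_start + r$element_length + 4)
    expect_identical(left, r$tsd)
    expect_identical(right, r$tsd)
  }
})
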