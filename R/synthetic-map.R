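#' Generate a binned genetic map with markers and planted translocations
#'
#' Divides each chromosome into `bins_per_chromosome` equal physical
#' windows (cM labels 0, 10, 20, ...) and extracts `markers_per_bin`
#' genome-unique marker sequences from each window. A planted translocation
#' reassigns the map entries of all markers covering a contiguous block of
#' gene copies on `from_chr` to the destination chromosome `to_chr`
#' (keeping their cM label), emulating a mapping population in which that
#' block segregates with another chromosome: the affected triads become
#' outliers whose one member maps outside its homoeologous group.
#'
#' @param sim A `synthetic_genome` from [generate_genome()].
#' @param bins_per_chromosome Bins per chromosome (default 4).
#' @param markers_per_bin Unique markers extracted per bin (default 2).
#' @param marker_length Marker length in bp, 31-100 (default 61).
#' @param translocations Optional data frame (`from_chr`, `to_chr`,
#'   `n_triads`): for each row, a contiguous block of `n_triads` gene
#'   copies on `from_chr`, all within one bin window, is remapped to
#'   `to_chr`.
#' @param genic_markers If `TRUE` (default), one additional genome-unique
#'   marker is extracted from within every gene copy, so each triad member
#'   can be anchored to a bin individually. Gene copies for which no
#'   unique substring exists (e.g. at zero divergence) are skipped with a
#'   message.
#' @param max_tries Sampling attempts per marker before giving up.
#' @param seed Integer seed.
#' @return List with `map` (a [genetic_map()]), `marker_seqs` (named
#'   character vector), `marker_truth` (tibble: `marker_id`,
#'   `true_chromosome`, `position`, `cM_bin`), `bins` (window coordinates)
#'   and `translocation_truth` (tibble per planted event: `source_chromosome`
#'   = `to_chr`, `source_cM_bin`, `target_chromosome` = `from_chr`,
#'   `triad_ids`, `n_triads`).
#' @export
generate_map <- function(sim, bins_per_chromosome = 4, markers_per_bin = 2,
                         marker_length = 61, translocations = NULL,
                         genic_markers = TRUE, max_tries = 200, seed = 1) {
  stopifnot(inherits(sim, "synthetic_genome"))
  if (marker_length < 31 || marker_length > 100) {
    stop("marker_length must be between 31 and 100 bp")
  }
  set.seed(seed)
  genome <- sim$genome
  subject <- Biostrings::DNAStringSet(genome)

  is_unique <- function(seq) {
    pat <- Biostrings::DNAString(seq)
    n <- sum(Biostrings::vcountPattern(pat, subject)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), subject))
    n == 1
  }

  marker_rows <- list()
  marker_seqs <- character()
  bin_rows <- list()
  m_id <- 0L
  for (chrom in names(genome)) {
    len <- nchar(genome[[chrom]])
    edges <- floor(seq(1, len + 1, length.out = bins_per_chromosome + 1))
    for (b in seq_len(bins_per_chromosome)) {
      w_start <- edges[b]
      w_end <- edges[b + 1] - 1L
      cm <- as.character((b - 1L) * 10L)
      bin_rows[[length(bin_rows) + 1]] <- tibble(
        chromosome = chrom, cM_bin = cm, window_start = w_start,
        window_end = w_end)
      found <- 0L
      tries <- 0L
      while (found < markers_per_bin) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("could not find ", markers_per_bin,
               " unique markers in bin ", chrom, ":", cm,
               "; fewer unique substrings available than requested")
        }
        p <- sample(w_start:(w_end - marker_length + 1L), 1)
        cand <- substr(genome[[chrom]], p, p + marker_length - 1L)
        if (grepl("[^ACGT]", cand) || !is_unique(cand)) next
        m_id <- m_id + 1L
        id <- sprintf("mk%04d", m_id)
        marker_seqs[[id]] <- cand
        marker_rows[[length(marker_rows) + 1]] <- tibble(
          marker_id = id, chromosome = chrom, cM_bin = cm,
          true_chromosome = chrom, position = p)
        found <- found + 1L
      }
    }
  }
  markers <- bind_rows(marker_rows)
  bins <- bind_rows(bin_rows)

  if (genic_markers) {
    members <- sim$truth$members
    skipped <- character()
    for (i in seq_len(nrow(members))) {
      mem <- members[i, ]
      lo <- mem$start
      hi <- mem$end - marker_length + 1L
      if (hi < lo) next
      chrom <- mem$chromosome
      chr_bins <- bins %>% filter(.data$chromosome == chrom)
      got <- FALSE
      for (tries in seq_len(max_tries)) {
        p <- if (hi > lo) sample(lo:hi, 1) else lo
        cand <- substr(genome[[chrom]], p, p + marker_length - 1L)
        if (grepl("[^ACGT]", cand) || !is_unique(cand)) next
        b <- findInterval(p, chr_bins$window_start)
        m_id <- m_id + 1L
        id <- paste0("gm_", mem$gene_id)
        marker_seqs[[id]] <- cand
        markers <- bind_rows(markers, tibble(
          marker_id = id, chromosome = chrom,
          cM_bin = chr_bins$cM_bin[b], true_chromosome = chrom,
          position = p))
        got <- TRUE
        break
      }
      if (!got) skipped <- c(skipped, mem$gene_id)
    }
    if (length(skipped)) {
      message("no unique genic marker found for ", length(skipped),
              " gene cop(ies); skipped")
    }
  }

  transloc_truth <- tibble(source_chromosome = character(),
                           source_cM_bin = character(),
                           target_chromosome = character(),
                           triad_ids = character(), n_triads = integer())
  if (!is.null(translocations)) {
    translocations <- as_tibble(translocations)
    members <- sim$truth$members
    for (i in seq_len(nrow(translocations))) {
      tr <- translocations[i, ]
      on_chr <- members %>%
        filter(.data$chromosome == tr$from_chr) %>%
        arrange(.data$start)
      if (nrow(on_chr) == 0) stop("no genes on chromosome ", tr$from_chr)
      chr_bins <- bins %>% filter(.data$chromosome == tr$from_chr)
      block <- NULL
      for (b in seq_len(nrow(chr_bins))) {
        in_bin <- on_chr %>%
          filter(.data$start >= chr_bins$window_start[b],
                 .data$end <= chr_bins$window_end[b])
        if (nrow(in_bin) >= tr$n_triads) {
          block <- in_bin[seq_len(tr$n_triads), ]
          block_bin <- chr_bins$cM_bin[b]
          break
        }
      }
      if (is.null(block)) {
        stop("no bin window on ", tr$from_chr, " holds ", tr$n_triads,
             " complete gene copies; use fewer triads or fewer bins")
      }
      lo <- min(block$start)
      hi <- max(block$end)
      affected <- markers$chromosome == tr$from_chr &
        markers$position >= lo & markers$position + marker_length - 1L <= hi
      # markers inside the moved block follow it onto the destination
      # chromosome in the map; their cM label is retained
      markers$chromosome[affected] <- tr$to_chr
      transloc_truth <- bind_rows(transloc_truth, tibble(
        source_chromosome = tr$to_chr, source_cM_bin = block_bin,
        target_chromosome = tr$from_chr,
        triad_ids = paste(sort(block$triad_id), collapse = ","),
        n_triads = as.integer(tr$n_triads),
        block_start = lo, block_end = hi))
    }
  }

  list(
    map = genetic_map(markers[, c("marker_id", "chromosome", "cM_bin")]),
    marker_seqs = marker_seqs,
    marker_truth = markers[, c("marker_id", "true_chromosome", "position", "cM_bin")],
    bins = bins,
    translocation_truth = transloc_truth
  )
}

#' Map bins of each triad member
#'
#' Looks up, for every triad member gene, the map assignment of the
#' markers located within the gene's span (its genic marker, plus any
#' window markers that happen to fall inside the gene). A member gets a
#' bin only when its markers agree on a single (chromosome, cM) pair;
#' members without markers, or with conflicting marker assignments, are
#' returned with `NA` bins.
#'
#' @param sim A `synthetic_genome`.
#' @param map_result Output of [generate_map()].
#' @return Tibble (`triad_id`, `subgenome`, `gene_id`, `chromosome`,
#'   `cM_bin`) suitable for [detect_translocations()].
#' @export
triad_member_bins <- function(sim, map_result) {
  stopifnot(inherits(sim, "synthetic_genome"))
  members <- sim$truth$members
  mk <- left_join(map_result$marker_truth[, c("marker_id", "true_chromosome", "position")],
                  map_result$map$markers[, c("marker_id", "chromosome", "cM_bin")],
                  by = "marker_id")
  rows <- lapply(seq_len(nrow(members)), function(i) {
    mem <- members[i, ]
    inside <- mk %>%
      filter(.data$true_chromosome == mem$chromosome,
             .data$position >= mem$start,
             .data$position <= mem$end)
    assigned <- distinct(inside[, c("chromosome", "cM_bin")])
    tibble(triad_id = mem$triad_id, subgenome = mem$subgenome,
           gene_id = mem$gene_id,
           chromosome = if (nrow(assigned) == 1) assigned$chromosome else NA_character_,
           cM_bin = if (nrow(assigned) == 1) as.character(assigned$cM_bin) else NA_character_)
  })
  bind_rows(rows)
}
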