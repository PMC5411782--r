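#' Configuration for the synthetic allohexaploid genome
#'
#' Bundles and validates the parameters of [generate_genome()]. The
#' defaults emulate a miniature hexaploid wheat-like genome: three
#' subgenomes (A, B, D) of seven chromosomes each, every gene present as a
#' homoeologous triad (one copy per subgenome) with controlled sequence
#' divergence between copies, interspersed repeat elements flanked by
#' target-site duplications, and roughly 2 Mb of total sequence.
#'
#' @param n_triads Number of homoeologous gene triads (default 140).
#' @param subgenomes Subgenome labels (default `c("A","B","D")`).
#' @param chromosomes_per_subgenome Homoeologous groups (default 7).
#' @param homoeolog_divergence Per-bp substitution rate between subgenome
#'   copies of a gene, in \[0, 0.3\] (default 0.02).
#' @param repeat_fraction Approximate fraction of the genome drawn from a
#'   randomly generated repeat library, in \[0, 0.9\] (default 0.15).
#' @param tsd_length Target-site duplication length in bp flanking each
#'   inserted repeat element (default 5).
#' @param n_exons Exons per gene (default 4; at least 4 supports all
#'   alternative-splicing event types).
#' @param exon_length,intron_length Length ranges in bp (min, max).
#' @param intergenic_length Spacer length between genes in bp (default 2500).
#' @param repeat_element_length Repeat element length range in bp.
#' @param n_repeat_elements Size of the generated repeat library.
#' @param deletions Optional data frame (`triad_id`, `subgenome`) of planted
#'   homoeolog deletions; those gene copies are omitted from the genome.
#'   Triad ids are `t001`, `t002`, ...
#' @param seed Integer seed; all outputs are byte-identical for a fixed
#'   seed.
#' @return A validated list of class `genome_config`.
#' @export
genome_config <- function(n_triads = 140, subgenomes = c("A", "B", "D"),
                          chromosomes_per_subgenome = 7,
                          homoeolog_divergence = 0.02,
                          repeat_fraction = 0.15, tsd_length = 5,
                          n_exons = 4, exon_length = c(120, 300),
                          intron_length = c(80, 200),
                          intergenic_length = 2500,
                          repeat_element_length = c(1000, 5000),
                          n_repeat_elements = 8,
                          deletions = NULL, seed = 1) {
  fail <- function(field, why) {
    stop("invalid configuration: ", field, " ", why, call. = FALSE)
  }
  if (length(n_triads) != 1 || n_triads < 1) fail("n_triads", "must be >= 1")
  if (length(subgenomes) < 1 || anyDuplicated(subgenomes)) {
    fail("subgenomes", "must be distinct labels")
  }
  if (chromosomes_per_subgenome < 1) fail("chromosomes_per_subgenome", "must be >= 1")
  if (homoeolog_divergence < 0 || homoeolog_divergence > 0.3) {
    fail("homoeolog_divergence", "must be in [0, 0.3]")
  }
  if (repeat_fraction < 0 || repeat_fraction > 0.9) {
    fail("repeat_fraction", "must be in [0, 0.9]")
  }
  if (tsd_length < 0) fail("tsd_length", "must be >= 0")
  if (n_exons < 1) fail("n_exons", "must be >= 1")
  if (intergenic_length < 100) fail("intergenic_length", "must be >= 100 bp")
  cfg <- list(
    n_triads = as.integer(n_triads), subgenomes = subgenomes,
    chromosomes_per_subgenome = as.integer(chromosomes_per_subgenome),
    homoeolog_divergence = homoeolog_divergence,
    repeat_fraction = repeat_fraction, tsd_length = as.integer(tsd_length),
    n_exons = as.integer(n_exons), exon_length = exon_length,
    intron_length = intron_length,
    intergenic_length = as.integer(intergenic_length),
    repeat_element_length = repeat_element_length,
    n_repeat_elements = as.integer(n_repeat_elements),
    deletions = if (is.null(deletions)) NULL else as_tibble(deletions),
    seed = as.integer(seed)
  )
  class(cfg) <- "genome_config"
  cfg
}

# substitutions at the given per-bp rate; the replacement base always
# differs from the original
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      chars[i] <- sample(setdiff(bases, chars[i]), 1)
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic allohexaploid genome with ground truth
#'
#' Builds chromosome sequences, gene models and truth tables for a
#' miniature genome in which every gene exists as a homoeologous triad
#' (one copy per subgenome, unless deleted by configuration). Ancestral
#' gene sequences and exon-intron structures are sampled once per triad;
#' each subgenome copy then differs from the ancestor only by substitutions
#' sampled at the configured divergence rate, so copies are colinear.
#' Intergenic spacers receive repeat-library insertions flanked by
#' identical target-site duplications.
#'
#' @param config A [genome_config()].
#' @return An object of class `synthetic_genome`: list with
#'   * `genome`: named character vector of chromosome sequences (`1A` ...
#'     `7D`);
#'   * `gene_models`: exon table (`gene_id`, `transcript_id`, `seqid`,
#'     `strand`, `type` exon/CDS, `start`, `end`, `phase`);
#'   * `truth`: list with `triads` and `members` (triad membership and
#'     member coordinates), `ancestors` (the unmutated ancestral gene
#'     sequences), `repeats` (insertion coordinates and TSDs), and the
#'     `config`.
#' @export
generate_genome <- function(config = genome_config()) {
  stopifnot(inherits(config, "genome_config"))
  set.seed(config$seed)
  n_groups <- config$chromosomes_per_subgenome
  sgs <- config$subgenomes
  chroms <- as.vector(outer(seq_len(n_groups), sgs, paste0))

  triad_ids <- sprintf("t%03d", seq_len(config$n_triads))
  groups <- ((seq_len(config$n_triads) - 1) %% n_groups) + 1

  # ancestral structures: exon/intron lengths and strand per triad
  ancestors <- lapply(seq_len(config$n_triads), function(i) {
    ex <- sample(config$exon_length[1]:config$exon_length[2], config$n_exons,
                 replace = TRUE)
    intr <- if (config$n_exons > 1) {
      sample(config$intron_length[1]:config$intron_length[2],
             config$n_exons - 1, replace = TRUE)
    } else integer()
    list(exon_len = ex, intron_len = intr,
         strand = sample(c("+", "-"), 1),
         seq = random_dna(sum(ex) + sum(intr)))
  })

  # repeat library and insertion plan
  rep_lens <- sample(config$repeat_element_length[1]:config$repeat_element_length[2],
                     config$n_repeat_elements, replace = TRUE)
  rep_lib <- vapply(rep_lens, random_dna, "")
  names(rep_lib) <- sprintf("rep%02d", seq_along(rep_lib))
  base_len <- sum(vapply(ancestors, function(a) nchar(a$seq), 0)) * length(sgs) +
    config$intergenic_length * (config$n_triads * length(sgs) + n_groups * length(sgs))
  target_rep_bases <- config$repeat_fraction / (1 - config$repeat_fraction) * base_len
  n_spacers_total <- config$n_triads * length(sgs) + n_groups * length(sgs)
  insert_prob <- min(1, target_rep_bases / (mean(rep_lens) * n_spacers_total))

  deletions <- config$deletions
  is_deleted <- function(tid, sg) {
    !is.null(deletions) &&
      any(deletions$triad_id == tid & deletions$subgenome == sg)
  }

  genome <- character()
  gene_rows <- list()
  triad_rows <- list()
  repeat_rows <- list()

  spacer <- function(chrom, at) {
    s <- random_dna(config$intergenic_length)
    if (runif(1) < insert_prob) {
      el <- sample(names(rep_lib), 1)
      p <- sample.int(nchar(s) - config$tsd_length, 1)
      tsd <- substr(s, p, p + config$tsd_length - 1)
      s <- paste0(substr(s, 1, p + config$tsd_length - 1), rep_lib[[el]],
                  substr(s, p, nchar(s)))
      repeat_rows[[length(repeat_rows) + 1]] <<- tibble(
        chromosome = chrom, element = el,
        element_start = at + p + config$tsd_length - 1L,
        element_length = nchar(rep_lib[[el]]), tsd = tsd)
    }
    s
  }

  for (sg in sgs) {
    for (g in seq_len(n_groups)) {
      chrom <- paste0(g, sg)
      idx <- which(groups == g)
      parts <- character()
      pos <- 1L
      gene_no <- 0L
      for (i in idx) {
        sp <- spacer(chrom, pos)
        parts <- c(parts, sp)
        pos <- pos + nchar(sp)
        tid <- triad_ids[i]
        if (is_deleted(tid, sg)) next
        anc <- ancestors[[i]]
        gseq <- mutate_sequence(anc$seq, config$homoeolog_divergence)
        gene_id <- paste0("g_", tid, "_", sg)
        gene_rows[[length(gene_rows) + 1]] <- gene_model_rows(
          gene_id, chrom, pos, anc, gseq)
        triad_rows[[length(triad_rows) + 1]] <- tibble(
          triad_id = tid, subgenome = sg, gene_id = gene_id,
          group = g, chromosome = chrom, start = pos,
          end = pos + nchar(gseq) - 1L, strand = anc$strand)
        parts <- c(parts, gseq)
        pos <- pos + nchar(gseq)
        gene_no <- gene_no + 1L
      }
      sp <- spacer(chrom, pos)
      parts <- c(parts, sp)
      genome[[chrom]] <- paste(parts, collapse = "")
    }
  }
  genome <- genome[chroms]

  gene_models <- bind_rows(gene_rows)
  members <- bind_rows(triad_rows)
  triads <- members %>%
    select("triad_id", "subgenome", "gene_id") %>%
    pivot_wider(names_from = "subgenome", values_from = "gene_id") %>%
    left_join(distinct(members[, c("triad_id", "group")]), by = "triad_id")

  out <- list(
    genome = genome,
    gene_models = gene_models,
    truth = list(
      triads = triads,
      members = members,
      ancestors = tibble(
        triad_id = triad_ids,
        strand = vapply(ancestors, `[[`, "", "strand"),
        seq = vapply(ancestors, `[[`, "", "seq")),
      repeats = bind_rows(repeat_rows),
      config = config
    )
  )
  class(out) <- "synthetic_genome"
  out
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d chromosomes, %g bp, %d genes (%d triads)\n",
              length(x$genome), sum(nchar(x$genome)),
              length(unique(x$gene_models$gene_id)),
              nrow(x$truth$triads)))
  invisible(x)
}

# exon/CDS rows for one gene copy placed at `offset` on `chrom`; the CDS
# covers the exons, trimmed at the mRNA 3' end so its length is a multiple
# of three, with GFF3 phases accumulated in mRNA order
gene_model_rows <- function(gene_id, chrom, offset, anc, gseq) {
  n <- length(anc$exon_len)
  starts <- integer(n)
  ends <- integer(n)
  p <- offset
  for (e in seq_len(n)) {
    starts[e] <- p
    ends[e] <- p + anc$exon_len[e] - 1L
    p <- ends[e] + 1L + if (e < n) anc$intron_len[e] else 0L
  }
  tx_id <- paste0(gene_id, ".1")
  exons <- tibble(gene_id = gene_id, transcript_id = tx_id, seqid = chrom,
                  strand = anc$strand, type = "exon",
                  start = starts, end = ends, phase = NA_integer_)
  cds <- cds_rows(exons)
  bind_rows(exons, cds)
}

# CDS rows derived from exon rows of one transcript: trim the mRNA 3' end
# to a multiple of 3 and assign phases
cds_rows <- function(exons) {
  exons <- exons[order(exons$start), ]
  widths <- exons$end - exons$start + 1L
  extra <- sum(widths) %% 3L
  cds <- exons
  cds$type <- "CDS"
  if (extra > 0) {
    if (exons$strand[[1]] == "+") {
      cds$end[nrow(cds)] <- cds$end[nrow(cds)] - extra
    } else {
      cds$start[1] <- cds$start[1] + extra
    }
  }
  ord <- if (exons$strand[[1]] == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  cum <- 0L
  for (i in ord) {
    cds$phase[i] <- (3L - (cum %% 3L)) %% 3L
    cum <- cum + cds$end[i] - cds$start[i] + 1L
  }
  cds
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based inclusive coordinates)
#' from an exon table. Output is deterministic: features are ordered by
#' sequence, gene start and type.
#'
#' @param gene_models Exon table as produced by [generate_genome()]
#'   (columns `gene_id`, `transcript_id`, `seqid`, `strand`, `type`,
#'   `start`, `end`, optionally `phase`).
#' @param path Output file path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gene_models, path, source = "polyqc") {
  gm <- as_tibble(gene_models)
  if (!"phase" %in% names(gm)) gm$phase <- NA_integer_
  lines <- c("##gff-version 3")
  genes <- gm %>%
    group_by(.data$gene_id, .data$seqid, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    arrange(.data$seqid, .data$start, .data$gene_id)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$seqid, source, g$start, g$end, g$strand, g$gene_id))
    rows <- gm %>% filter(.data$gene_id == g$gene_id)
    for (tx in sort(unique(rows$transcript_id))) {
      tr <- rows %>% filter(.data$transcript_id == tx)
      lines <- c(lines, sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                g$seqid, source, min(tr$start), max(tr$end),
                                g$strand, tx, g$gene_id))
      tr <- tr %>% arrange(factor(.data$type, levels = c("exon", "CDS")),
                           .data$start)
      lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
                                tr$seqid, source, tr$type, tr$start, tr$end,
                                tr$strand,
                                ifelse(is.na(tr$phase), ".", as.character(tr$phase)),
                                tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
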