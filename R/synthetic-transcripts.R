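#' Generate alternative transcripts realizing known splicing events
#'
#' For each selected gene, samples one event type from `as_event_mix` and
#' constructs an alternative transcript that realizes exactly that event
#' relative to the gene's representative isoform:
#' * `IR` - the alternative transcript retains the intron between the
#'   second and third exons (in mRNA order);
#' * `ES` - the alternative transcript skips an internal exon, keeping the
#'   outer boundaries of the flanking introns;
#' * `A5SS` / `A3SS` - the donor (acceptor) of the first intron in mRNA
#'   orientation is shifted by `shift` bp, on the strand-correct side;
#' * `MXE` - the pair uses mutually exclusive internal exons: the
#'   representative keeps the second exon and drops the third, the
#'   alternative keeps the third and drops the second (for MXE genes the
#'   emitted representative differs from the full gene model).
#'
#' Genes with too few exons for the sampled event (ES needs 3, MXE needs
#' 4) are skipped with a message and reported.
#'
#' @param gene_models Exon table from [generate_genome()].
#' @param as_event_mix Named proportions over `IR`, `A3SS`, `ES`, `A5SS`,
#'   `MXE`; must sum to 1. The default mirrors event frequencies typical
#'   of grass transcriptomes, where intron retention dominates.
#' @param genes Optional character vector of gene ids to process (default:
#'   all genes in `gene_models`).
#' @param shift Donor/acceptor shift in bp for A5SS/A3SS (default 9; must
#'   be smaller than the shortest exon and intron).
#' @param seed Integer seed.
#' @return List with `transcripts` (named list: per gene, the list of
#'   [transcript()] isoforms, representative first), `exon_table` (exon
#'   rows of all isoforms), `labels` (tibble: `gene_id`, `alt_id`,
#'   `event`) and `skipped` (tibble: `gene_id`, `event`, `reason`).
#' @export
generate_transcripts <- function(gene_models,
                                 as_event_mix = c(IR = 0.34, A3SS = 0.27,
                                                  ES = 0.20, A5SS = 0.19),
                                 genes = NULL, shift = 9, seed = 1) {
  events_all <- c("IR", "A3SS", "ES", "A5SS", "MXE")
  if (!all(names(as_event_mix) %in% events_all)) {
    stop("as_event_mix names must be among: ", paste(events_all, collapse = ", "))
  }
  if (abs(sum(as_event_mix) - 1) > 1e-8) stop("as_event_mix must sum to 1")
  gm <- as_tibble(gene_models) %>% filter(.data$type == "exon")
  if (is.null(genes)) genes <- unique(gm$gene_id)
  set.seed(seed)
  mix <- as_event_mix[events_all]
  mix[is.na(mix)] <- 0
  names(mix) <- events_all
  sampled <- sample(events_all, length(genes), replace = TRUE, prob = mix)

  transcripts <- list()
  label_rows <- list()
  skip_rows <- list()
  exon_rows <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ev <- sampled[gi]
    rows <- gm %>% filter(.data$gene_id == g) %>% arrange(.data$start)
    strand <- rows$strand[[1]]
    seqid <- rows$seqid[[1]]
    n <- nrow(rows)
    need <- switch(ev, ES = 3L, MXE = 4L, 2L)
    if (n < need) {
      message("gene ", g, ": ", ev, " needs >= ", need, " exons (has ", n,
              "); skipped")
      skip_rows[[length(skip_rows) + 1]] <- tibble(
        gene_id = g, event = ev, reason = paste0("needs>=", need, "exons"))
      next
    }
    ex <- rows[, c("start", "end")]
    # mRNA-order index of the i-th exon: reversed on the minus strand
    mrna <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    rep_ex <- ex
    alt_ex <- ex
    if (ev == "IR") {
      # retain the intron after the 2nd exon in mRNA order
      i <- sort(mrna[2:3])
      alt_ex <- rbind(ex[seq_len(i[1] - 1), , drop = FALSE],
                      data.frame(start = ex$start[i[1]], end = ex$end[i[2]]),
                      ex[seq(i[2] + 1, length.out = n - i[2]), , drop = FALSE])
    } else if (ev == "ES") {
      alt_ex <- ex[-mrna[2], , drop = FALSE]
    } else if (ev == "MXE") {
      rep_ex <- ex[-mrna[3], , drop = FALSE]
      alt_ex <- ex[-mrna[2], , drop = FALSE]
    } else {
      # shift one boundary of the first intron in mRNA orientation
      first_two <- sort(mrna[1:2])
      left_ex <- first_two[1]   # exon on the genomic left of that intron
      right_ex <- first_two[2]
      genomic_right <- (strand == "+") == (ev == "A3SS")
      if (genomic_right) {
        alt_ex$start[right_ex] <- alt_ex$start[right_ex] + shift
      } else {
        alt_ex$end[left_ex] <- alt_ex$end[left_ex] - shift
      }
    }
    rep_tx <- transcript(rep_ex, strand = strand, id = paste0(g, ".1"),
                         seqid = seqid)
    alt_tx <- transcript(alt_ex, strand = strand, id = paste0(g, ".2"),
                         seqid = seqid)
    transcripts[[g]] <- list(rep_tx, alt_tx)
    label_rows[[length(label_rows) + 1]] <- tibble(
      gene_id = g, alt_id = alt_tx$id, event = ev)
    for (tx in list(rep_tx, alt_tx)) {
      exon_rows[[length(exon_rows) + 1]] <- tibble(
        gene_id = g, transcript_id = tx$id, seqid = seqid, strand = strand,
        type = "exon", start = tx$exons$start, end = tx$exons$end,
        phase = NA_integer_)
    }
  }
  list(
    transcripts = transcripts,
    exon_table = bind_rows(exon_rows),
    labels = bind_rows(label_rows),
    skipped = if (length(skip_rows)) bind_rows(skip_rows) else
      tibble(gene_id = character(), event = character(), reason = character())
  )
}
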