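#' Assign gene-model confidence classes and evidence ranks
#'
#' Classifies gene models as high confidence (HC) or low confidence (LC)
#' from protein-homology and transcriptome evidence, and assigns evidence
#' ranks within HC:
#' * LC if and only if the best homolog coverage is below 0.60, or the gene
#'   lacks wheat transcript support, or it is repeat-associated - every
#'   applicable reason is reported (`short-protein`, `no-transcript`,
#'   `repeat`, in that order);
#' * within HC, protein rank P1 marks genes whose predicted protein spans
#'   at least 80% of the best homolog; transcript rank T1 marks full-length
#'   support by a PacBio transcript and T2 full support by assembled
#'   RNA-seq in its absence.
#'
#' @param evidence Data frame with columns `gene_id`, `coverage` (fraction
#'   of best-homolog length covered, in \[0,1\]), and logical flags
#'   `pacbio_full`, `rnaseq_full`, `repeat_associated`,
#'   `wheat_transcript_support`.
#' @param lc_coverage Coverage below which a gene is LC (default 0.60).
#' @param p1_coverage Coverage at or above which an HC gene is P1
#'   (default 0.80).
#' @return Tibble: `gene_id`, `tier` (HC/LC), `protein_rank` (`"P1"` or
#'   `NA`), `transcript_rank` (`"T1"`, `"T2"` or `NA`), `lc_reason`
#'   (comma-separated, `NA` for HC genes).
#' @export
assign_confidence <- function(evidence, lc_coverage = 0.60, p1_coverage = 0.80) {
  evidence <- as_tibble(evidence)
  need <- c("gene_id", "coverage", "pacbio_full", "rnaseq_full",
            "repeat_associated", "wheat_transcript_support")
  miss <- setdiff(need, names(evidence))
  if (length(miss)) stop("evidence lacks column(s): ", paste(miss, collapse = ", "))
  for (col in need[-1]) {
    bad <- evidence$gene_id[is.na(evidence[[col]])]
    if (length(bad)) {
      stop("missing evidence '", col, "' for gene(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (any(evidence$coverage < 0 | evidence$coverage > 1)) {
    stop("coverage must be a fraction in [0, 1]")
  }
  evidence %>%
    mutate(
      lc_short = .data$coverage < lc_coverage,
      lc_notx = !.data$wheat_transcript_support,
      lc_rep = .data$repeat_associated,
      tier = ifelse(.data$lc_short | .data$lc_notx | .data$lc_rep, "LC", "HC"),
      protein_rank = ifelse(.data$tier == "HC" & .data$coverage >= p1_coverage,
                            "P1", NA_character_),
      transcript_rank = ifelse(
        .data$tier == "HC" & .data$pacbio_full, "T1",
        ifelse(.data$tier == "HC" & .data$rnaseq_full, "T2", NA_character_)),
      lc_reason = ifelse(.data$tier == "LC", mapply(function(s, t, r) {
        paste(c("short-protein", "no-transcript", "repeat")[c(s, t, r)],
              collapse = ",")
      }, .data$lc_short, .data$lc_notx, .data$lc_rep), NA_character_)
    ) %>%
    select("gene_id", "tier", "protein_rank", "transcript_rank", "lc_reason")
}

#' Filter annotation-transfer alignments
#'
#' Retains gene-model transfer alignments meeting stringent thresholds:
#' coverage of at least `min_coverage` and identity of at least
#' `min_identity` (both inclusive).
#'
#' @param alignments Data frame with numeric columns `coverage` and
#'   `identity` (fractions).
#' @param min_coverage Minimum alignment coverage (default 0.90).
#' @param min_identity Minimum alignment identity (default 0.95).
#' @return The retained rows, with attribute `n_input` for rate reporting.
#' @export
transfer_filter <- function(alignments, min_coverage = 0.90,
                            min_identity = 0.95) {
  alignments <- as_tibble(alignments)
  if (!all(c("coverage", "identity") %in% names(alignments))) {
    stop("alignments must have columns coverage and identity")
  }
  out <- filter(alignments, .data$coverage >= min_coverage,
                .data$identity >= min_identity)
  attr(out, "n_input") <- nrow(alignments)
  out
}
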