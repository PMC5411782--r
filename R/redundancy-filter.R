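#' Two-tiered scaffold redundancy filter
#'
#' Post-scaffolding screen that removes short, redundant sequences while
#' minimising the loss of unique sequence content. Scaffolds are processed
#' in decreasing length order (length ties broken by lexicographic id so
#' the result is deterministic). Scaffolds at or above the length gate are
#' always retained. A scaffold below the gate is removed if and only if at
#' least `redundancy_threshold` of its distinct canonical k-mers already
#' occur in the cumulative k-mer set of the scaffolds retained so far.
#'
#' A short scaffold that contributes no k-mers at all (shorter than `k`, or
#' all windows contain non-ACGT symbols) has no unique content by
#' definition; it is removed with `redundant_fraction = 1` and a message.
#'
#' @param scaffolds Named character vector or `DNAStringSet`.
#' @param min_len Length gate in bp (default 500); scaffolds at least this
#'   long are always kept.
#' @param k Canonical k-mer length (odd, default 31).
#' @param redundancy_threshold Fraction in (0, 1] of a short scaffold's
#'   distinct k-mers that must be already represented for it to be dropped
#'   (default 0.95).
#' @return An object of class `filter_report`: a list with
#'   * `report`: tibble (`scaffold_id`, `length`, `kept`, `reason` one of
#'     `kept-long`/`kept-novel`/`removed-redundant`, `redundant_fraction`,
#'     `n_kmers`);
#'   * `kept_ids`, `removed_redundant_ids`;
#'   * `unique_content_lost`: distinct k-mers found only in removed
#'     scaffolds;
#'   * `n50_before`, `n50_after`;
#'   * `filtered`: named character vector of retained scaffolds, in input
#'     order.
#' @export
filter_scaffolds <- function(scaffolds, min_len = 500, k = 31,
                             redundancy_threshold = 0.95) {
  check_k(k)
  if (min_len < k) stop("min_len must be >= k")
  if (redundancy_threshold <= 0 || redundancy_threshold > 1) {
    stop("redundancy_threshold must be in (0, 1]")
  }
  scaffolds <- as_seq_character(scaffolds, "scaffolds")
  if (anyDuplicated(names(scaffolds))) stop("scaffold ids must be unique")
  lens <- nchar(scaffolds)
  ord <- order(-lens, names(scaffolds))
  seqs <- scaffolds[ord]
  always_keep <- nchar(seqs) >= min_len
  res <- cpp_redundancy_filter(unname(seqs), always_keep,
                               redundancy_threshold, as.integer(k))
  report <- tibble(
    scaffold_id = names(seqs),
    length = as.integer(nchar(seqs)),
    kept = res$keep,
    redundant_fraction = res$redundant_fraction,
    n_kmers = as.numeric(res$n_kmers)
  ) %>%
    mutate(reason = dplyr::case_when(
      .data$kept & .data$length >= min_len ~ "kept-long",
      .data$kept ~ "kept-novel",
      .data$n_kmers == 0 ~ "removed-short",
      TRUE ~ "removed-redundant"
    ))
  empties <- report$scaffold_id[report$reason == "removed-short"]
  if (length(empties)) {
    message(length(empties), " scaffold(s) contributed no k-mers (shorter than k): ",
            paste(utils::head(empties, 5), collapse = ", "))
  }
  kept_ids <- report$scaffold_id[report$kept]
  out <- list(
    report = report,
    kept_ids = kept_ids,
    removed_short_ids = report$scaffold_id[report$reason == "removed-short"],
    removed_redundant_ids = report$scaffold_id[report$reason == "removed-redundant"],
    unique_content_lost = res$unique_content_lost,
    n50_before = assembly_n50(lens),
    n50_after = assembly_n50(nchar(scaffolds[names(scaffolds) %in% kept_ids])),
    filtered = scaffolds[names(scaffolds) %in% kept_ids]
  )
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("scaffold redundancy filter\n")
  cat(sprintf("  input scaffolds      : %d (N50 %d)\n", nrow(x$report), x$n50_before))
  cat(sprintf("  kept                 : %d (N50 %d)\n", length(x$kept_ids), x$n50_after))
  cat(sprintf("  removed redundant    : %d\n", length(x$removed_redundant_ids)))
  cat(sprintf("  unique k-mers lost   : %g\n", x$unique_content_lost))
  invisible(x)
}
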