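#' TPM normalisation
#'
#' Transcripts-per-million: counts are divided by effective gene length in
#' kb, then each sample is scaled so its values sum to one million.
#'
#' @param counts Numeric matrix, genes x samples (rownames = gene ids).
#' @param lengths Numeric vector of effective lengths in bp, one per gene
#'   (recycled by name if named).
#' @return Numeric matrix of TPM values with the same dimensions.
#' @export
tpm_normalize <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) {
    stop("lengths must have one entry per gene")
  }
  if (any(is.na(lengths)) || any(lengths <= 0)) stop("gene lengths must be positive")
  lengths <- as.numeric(lengths)  # drop any array/dimnames attributes
  rate <- counts / (lengths / 1000)
  denom <- colSums(rate)
  denom[denom == 0] <- 1  # all-zero sample stays all-zero
  sweep(rate, 2, denom, "/") * 1e6
}

# member-by-condition mean tpm for one triad; members ordered A,B,D
triad_condition_means <- function(tpm, gene_ids, samples) {
  conds <- unique(samples$condition)
  m <- sapply(conds, function(cn) {
    cols <- samples$sample[samples$condition == cn]
    rowMeans(tpm[gene_ids, cols, drop = FALSE])
  })
  matrix(m, nrow = length(gene_ids), dimnames = list(gene_ids, conds))
}

check_samples <- function(tpm, samples) {
  samples <- as_tibble(samples)
  if (!all(c("sample", "condition") %in% names(samples))) {
    stop("samples must have columns sample, condition")
  }
  if (!all(samples$sample %in% colnames(tpm))) {
    stop("sample metadata refers to columns absent from the matrix")
  }
  reps <- dplyr::count(samples, .data$condition)
  if (any(reps$n < 2)) {
    warning("condition(s) with fewer than 2 replicates: ",
            paste(reps$condition[reps$n < 2], collapse = ", "),
            "; classification proceeds on means")
  }
  samples
}

check_triads <- function(triads) {
  triads <- as_tibble(triads)
  need <- c("triad_id", "A", "B", "D")
  if (!all(need %in% names(triads))) {
    stop("triads must have columns ", paste(need, collapse = ", "))
  }
  triads
}

#' Classify homoeolog triad expression balance
#'
#' A triad is expressed in a condition if at least one member's mean TPM is
#' at or above the background floor. An expressed triad is unbalanced in a
#' condition when the highest member mean exceeds `ratio_threshold` times
#' the lowest member mean; the members within `ratio_threshold` of the
#' maximum are reported as dominant. A triad with all members below the
#' floor in every condition is marked not expressed and excluded from the
#' balance summary.
#'
#' @param tpm TPM matrix, genes x samples.
#' @param triads Data frame (`triad_id`, `A`, `B`, `D`) of member gene ids.
#' @param samples Data frame (`sample`, `condition`).
#' @param floor Background expression level in TPM (default 2).
#' @param ratio_threshold Max/min member ratio above which a triad is
#'   called unbalanced (default 2).
#' @return A list with `per_condition` (tibble: `triad_id`, `condition`,
#'   `expressed`, `status` balanced/unbalanced/not-expressed, `dominant`
#'   comma-separated subgenome labels or `NA`) and `summary` (tibble:
#'   `triad_id`, `expressed`, `unbalanced_any`), plus the counts
#'   `n_expressed`, `n_unbalanced` and `unbalanced_pct`.
#' @export
classify_balance <- function(tpm, triads, samples, floor = 2,
                             ratio_threshold = 2) {
  triads <- check_triads(triads)
  samples <- check_samples(tpm, samples)
  members <- c("A", "B", "D")
  rows <- lapply(seq_len(nrow(triads)), function(i) {
    ids <- unlist(triads[i, members])
    mm <- triad_condition_means(tpm, ids, samples)
    apply_balance <- function(cn) {
      v <- mm[, cn]
      if (all(v < floor)) {
        return(tibble(condition = cn, expressed = FALSE,
                      status = "not-expressed", dominant = NA_character_))
      }
      unbal <- max(v) > ratio_threshold * min(v)
      dom <- if (unbal) {
        paste(members[v * ratio_threshold > max(v)], collapse = ",")
      } else NA_character_
      tibble(condition = cn, expressed = TRUE,
             status = if (unbal) "unbalanced" else "balanced", dominant = dom)
    }
    cbind(tibble(triad_id = triads$triad_id[i]),
          bind_rows(lapply(colnames(mm), apply_balance)))
  })
  per_condition <- as_tibble(bind_rows(rows))
  summary <- per_condition %>%
    group_by(.data$triad_id) %>%
    summarise(expressed = any(.data$expressed),
              unbalanced_any = any(.data$status == "unbalanced"))
  n_expressed <- sum(summary$expressed)
  n_unbalanced <- sum(summary$unbalanced_any)
  list(per_condition = per_condition, summary = summary,
       n_expressed = n_expressed, n_unbalanced = n_unbalanced,
       unbalanced_pct = if (n_expressed > 0) pct(n_unbalanced, n_expressed) else NA_real_)
}

#' Per-homoeolog stress response calls and triad patterns
#'
#' For each triad and each stress condition, the stress/control fold change
#' of each homoeolog is computed on replicate means after adding a
#' pseudocount. A homoeolog is UP when its fold change is greater than
#' `up_threshold` (strictly), DOWN when less than `down_threshold`
#' (strictly), and FLAT otherwise. The triad pattern is a pure function of
#' the three calls:
#' * `not-DE` - all three FLAT;
#' * `1-DE` - exactly one homoeolog UP or DOWN;
#' * `2-DE-same` / `3-DE-same` - two / three homoeologs changed, all in the
#'   same direction;
#' * `opposite` - at least two changed with opposing directions.
#'
#' @param tpm TPM matrix, genes x samples.
#' @param triads Data frame (`triad_id`, `A`, `B`, `D`).
#' @param samples Data frame (`sample`, `condition`).
#' @param control Name of the control condition (default `"control"`).
#' @param up_threshold,down_threshold Fold-change cut-offs (defaults 2 and
#'   0.5, both strict).
#' @param pseudocount Added to both means before the ratio (default 0.5).
#' @return A tibble with one row per triad x stress condition: `triad_id`,
#'   `condition`, `fc_A/B/D`, `call_A/B/D`, `pattern`.
#' @export
classify_stress <- function(tpm, triads, samples, control = "control",
                            up_threshold = 2, down_threshold = 0.5,
                            pseudocount = 0.5) {
  triads <- check_triads(triads)
  samples <- check_samples(tpm, samples)
  if (!control %in% samples$condition) {
    stop("control condition '", control, "' absent from sample metadata")
  }
  stress_conditions <- setdiff(unique(samples$condition), control)
  members <- c("A", "B", "D")
  rows <- lapply(seq_len(nrow(triads)), function(i) {
    ids <- unlist(triads[i, members])
    mm <- triad_condition_means(tpm, ids, samples)
    bind_rows(lapply(stress_conditions, function(cn) {
      fc <- (mm[, cn] + pseudocount) / (mm[, control] + pseudocount)
      calls <- homoeolog_call(fc, up_threshold, down_threshold)
      tibble(triad_id = triads$triad_id[i], condition = cn,
             fc_A = fc[[1]], fc_B = fc[[2]], fc_D = fc[[3]],
             call_A = calls[[1]], call_B = calls[[2]], call_D = calls[[3]],
             pattern = call_pattern(calls))
    }))
  })
  as_tibble(bind_rows(rows))
}

#' Fold-change calls for one homoeolog set
#' @param fc Numeric vector of stress/control fold changes.
#' @param up_threshold,down_threshold Strict cut-offs (defaults 2, 0.5).
#' @return Character vector of `"UP"`, `"DOWN"`, `"FLAT"`.
#' @export
homoeolog_call <- function(fc, up_threshold = 2, down_threshold = 0.5) {
  ifelse(fc > up_threshold, "UP", ifelse(fc < down_threshold, "DOWN", "FLAT"))
}

#' Triad pattern from three homoeolog calls
#' @param calls Character vector of three calls in `{UP, DOWN, FLAT}`.
#' @return One of `"not-DE"`, `"1-DE"`, `"2-DE-same"`, `"3-DE-same"`,
#'   `"opposite"`.
#' @export
call_pattern <- function(calls) {
  stopifnot(length(calls) == 3, all(calls %in% c("UP", "DOWN", "FLAT")))
  de <- calls[calls != "FLAT"]
  n <- length(de)
  if (n == 0) return("not-DE")
  if (n == 1) return("1-DE")
  if (length(unique(de)) > 1) return("opposite")
  if (n == 2) "2-DE-same" else "3-DE-same"
}

#' Pattern frequency table across conditions
#'
#' Tabulates triad patterns per condition, the data structure behind
#' stacked-bar summaries of differential homoeolog response. Frequencies
#' are reported over all triads and - excluding `not-DE` - over
#' differentially expressed triads.
#'
#' @param stress_calls Output of [classify_stress()].
#' @return Tibble: `condition`, `pattern`, `n`, `freq_all`, `freq_de`
#'   (`NA` for `not-DE`).
#' @export
pattern_frequencies <- function(stress_calls) {
  stress_calls %>%
    dplyr::count(.data$condition, .data$pattern) %>%
    group_by(.data$condition) %>%
    mutate(freq_all = .data$n / sum(.data$n),
           freq_de = ifelse(.data$pattern == "not-DE", NA_real_,
                            .data$n / sum(.data$n[.data$pattern != "not-DE"]))) %>%
    ungroup()
}

#' Find expression hotspot bins
#'
#' A genetic bin is a hotspot in a tissue when the median TPM of its genes
#' exceeds the threshold (strictly). Bins without genes are skipped.
#'
#' @param gene_tpm Named numeric vector (single tissue) or genes x tissues
#'   matrix of TPM values.
#' @param gene_bins Data frame (`gene_id`, `chromosome`, `cM_bin`).
#' @param threshold Median TPM a hotspot must exceed (default 20).
#' @return Tibble: `tissue`, `chromosome`, `cM_bin`, `n_genes`,
#'   `median_tpm` for hotspot bins only.
#' @export
find_hotspots <- function(gene_tpm, gene_bins, threshold = 20) {
  if (is.null(dim(gene_tpm))) {
    gene_tpm <- matrix(gene_tpm, ncol = 1,
                       dimnames = list(names(gene_tpm), "tissue1"))
  }
  gene_bins <- as_tibble(gene_bins)
  gene_bins <- filter(gene_bins, .data$gene_id %in% rownames(gene_tpm))
  out <- lapply(colnames(gene_tpm), function(ts) {
    gene_bins %>%
      mutate(tpm = gene_tpm[.data$gene_id, ts]) %>%
      group_by(.data$chromosome, .data$cM_bin) %>%
      summarise(n_genes = dplyr::n(), median_tpm = median(.data$tpm),
                .groups = "drop") %>%
      filter(.data$median_tpm > threshold) %>%
      mutate(tissue = ts, .before = 1)
  })
  bind_rows(out)
}

#' Detect candidate translocations from outlier triads
#'
#' An outlier triad has exactly one member whose map chromosome falls
#' outside the homoeologous group shared by the other two members.
#' Outliers are aggregated by the genetic bin the outlier member maps to
#' (the candidate source region) and by the chromosome the member would be
#' expected on (majority group + the member's subgenome). Bins supported by
#' at least `min_support` outlier triads are reported, sorted by support.
#'
#' @param member_bins Data frame with one row per triad member: `triad_id`,
#'   `subgenome` (A/B/D), `chromosome`, `cM_bin` (map assignment of the
#'   member's scaffold). Triads with unanchored members are skipped.
#' @param min_support Minimum outlier triads per candidate (default 3).
#' @return An object of class `translocation_result`: list with
#'   `candidates` (tibble: `source_chromosome`, `source_cM_bin`,
#'   `target_chromosome`, `n_support`, `triads` comma-separated) and
#'   `outliers` (per outlier triad detail).
#' @export
detect_translocations <- function(member_bins, min_support = 3) {
  member_bins <- as_tibble(member_bins)
  need <- c("triad_id", "subgenome", "chromosome", "cM_bin")
  if (!all(need %in% names(member_bins))) {
    stop("member_bins must have columns ", paste(need, collapse = ", "))
  }
  complete <- member_bins %>%
    filter(!is.na(.data$chromosome)) %>%
    group_by(.data$triad_id) %>%
    filter(dplyr::n() == 3) %>%
    ungroup()
  outliers <- complete %>%
    group_by(.data$triad_id) %>%
    group_modify(function(df, key) {
      groups <- chrom_group(df$chromosome)
      tab <- table(groups)
      if (length(tab) != 2 || !any(tab == 2)) return(tibble())
      maj <- names(tab)[tab == 2]
      i <- which(groups != maj)
      tibble(subgenome = df$subgenome[i],
             source_chromosome = df$chromosome[i],
             source_cM_bin = as.character(df$cM_bin[i]),
             target_chromosome = paste0(maj, df$subgenome[i]))
    }) %>%
    ungroup()
  if (nrow(outliers) == 0) {
    outliers <- tibble(triad_id = character(), subgenome = character(),
                       source_chromosome = character(),
                       source_cM_bin = character(),
                       target_chromosome = character())
  }
  candidates <- outliers %>%
    group_by(.data$source_chromosome, .data$source_cM_bin,
             .data$target_chromosome) %>%
    summarise(n_support = dplyr::n(),
              triads = paste(sort(.data$triad_id), collapse = ","),
              .groups = "drop") %>%
    filter(.data$n_support >= min_support) %>%
    arrange(desc(.data$n_support), .data$source_chromosome,
            .data$source_cM_bin)
  out <- list(candidates = candidates, outliers = outliers)
  class(out) <- "translocation_result"
  out
}

#' @export
print.translocation_result <- function(x, ...) {
  cat(sprintf("translocation detection: %d outlier triads, %d candidate(s)\n",
              nrow(x$outliers), nrow(x$candidates)))
  if (nrow(x$candidates)) print(as.data.frame(x$candidates[, 1:4]))
  invisible(x)
}
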