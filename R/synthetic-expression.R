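#' Simulate triad expression counts with planted patterns
#'
#' Generates a negative-binomial count matrix (genes x samples) for a set
#' of homoeolog triads under a paired control/stress design, with known
#' per-triad labels:
#' * each stress condition assigns every triad a response pattern drawn
#'   from `pattern_mix` over `{flat, 1-DE, 2-DE-same, 3-DE-same,
#'   opposite}`; differentially expressed members receive fold change
#'   `up_fold` (UP) or `down_fold` (DOWN), sampled directions balanced so
#'   planted folds stay unambiguous relative to the 2x / 0.5x call
#'   thresholds;
#' * a fraction `imbalance_fraction` of triads is given one dominant
#'   member at `dominance_fold` times the baseline of the other two.
#'
#' Counts are `NB(mu, size = 1/dispersion)` with
#' `mu = level * fold * length/1e3`; at `dispersion = 0` counts are the
#' rounded means, so downstream classification recovers the planted labels
#' exactly.
#'
#' @param triads Data frame (`triad_id`, `A`, `B`, `D`) of member gene ids
#'   (e.g. `sim$truth$triads`).
#' @param conditions Character vector of stress condition names; a
#'   `control` condition is always generated as the reference.
#' @param n_reps Replicates per condition (default 3).
#' @param pattern_mix Named proportions over the five patterns; must sum
#'   to 1. The default emulates a stress experiment in which 80% of triads
#'   do not respond and single-homoeolog responses dominate among those
#'   that do.
#' @param imbalance_fraction Fraction of triads with unbalanced baseline
#'   expression (default 0).
#' @param base_mean Mean baseline expression level per member (counts per
#'   kb; default 100). Baselines are jittered log-normally per triad.
#' @param up_fold,down_fold Planted fold changes (defaults 2.5 and 0.4,
#'   beyond the 2x/0.5x call thresholds).
#' @param dominance_fold Fold of the dominant member in unbalanced triads
#'   (default 4).
#' @param dispersion Negative-binomial dispersion (default 0.1); 0 gives
#'   deterministic rounded means.
#' @param gene_lengths Optional named vector of gene lengths in bp
#'   (default: 1000 for all genes).
#' @param seed Integer seed.
#' @return List with `counts` (matrix), `samples` (tibble: `sample`,
#'   `condition`, `replicate`), `gene_lengths`, and `labels` (list with
#'   `patterns`: `triad_id`, `condition`, `pattern`, `call_A/B/D`;
#'   `balance`: `triad_id`, `unbalanced`, `dominant`).
#' @export
generate_expression <- function(triads,
                                conditions = c("D.6h", "H.6h"),
                                n_reps = 3,
                                pattern_mix = c("flat" = 0.80, "1-DE" = 0.16,
                                                "2-DE-same" = 0.02,
                                                "3-DE-same" = 0.01,
                                                "opposite" = 0.01),
                                imbalance_fraction = 0,
                                base_mean = 100,
                                up_fold = 2.5, down_fold = 0.4,
                                dominance_fold = 4,
                                dispersion = 0.1,
                                gene_lengths = NULL,
                                seed = 1) {
  triads <- check_triads(triads)
  patterns <- c("flat", "1-DE", "2-DE-same", "3-DE-same", "opposite")
  if (!all(names(pattern_mix) %in% patterns)) {
    stop("pattern_mix names must be among: ", paste(patterns, collapse = ", "))
  }
  if (abs(sum(pattern_mix) - 1) > 1e-8) stop("pattern_mix must sum to 1")
  if (n_reps < 2) {
    warning("fewer than 2 replicates per condition; classification will ",
            "run on single-sample means")
  }
  set.seed(seed)
  members <- c("A", "B", "D")
  gene_ids <- as.vector(t(as.matrix(triads[, members])))
  if (is.null(gene_lengths)) {
    gene_lengths <- setNames(rep(1000, length(gene_ids)), gene_ids)
  }
  if (!all(gene_ids %in% names(gene_lengths))) {
    stop("gene_lengths must cover every triad member")
  }
  n_triads <- nrow(triads)
  all_conditions <- c("control", conditions)
  samples <- tidyr::expand_grid(condition = all_conditions,
                                replicate = seq_len(n_reps)) %>%
    mutate(sample = paste0(.data$condition, "_r", .data$replicate)) %>%
    select("sample", "condition", "replicate")

  # baseline member levels, with optional planted imbalance
  n_unbal <- round(imbalance_fraction * n_triads)
  unbal_idx <- if (n_unbal > 0) sort(sample.int(n_triads, n_unbal)) else integer()
  base_level <- matrix(rep(base_mean * exp(stats::rnorm(n_triads, 0, 0.3)), each = 3),
                       nrow = 3, dimnames = list(members, triads$triad_id))
  dominant <- rep(NA_character_, n_triads)
  for (i in unbal_idx) {
    d <- sample(members, 1)
    base_level[d, i] <- base_level[d, i] * dominance_fold
    dominant[i] <- d
  }

  # per-condition patterns and member folds
  mix <- pattern_mix[patterns]
  mix[is.na(mix)] <- 0
  names(mix) <- patterns
  label_rows <- list()
  fold <- array(1, dim = c(3, n_triads, length(all_conditions)),
                dimnames = list(members, triads$triad_id, all_conditions))
  for (cn in conditions) {
    pat <- sample(patterns, n_triads, replace = TRUE, prob = mix)
    # same-direction patterns draw from a balanced, shuffled UP/DOWN pool so
    # the library composition barely shifts between control and stress
    same_dir <- which(pat %in% c("1-DE", "2-DE-same", "3-DE-same"))
    dir_pool <- sample(rep(c("UP", "DOWN"), length.out = length(same_dir)))
    names(dir_pool) <- as.character(same_dir)
    for (i in seq_len(n_triads)) {
      calls <- c(A = "FLAT", B = "FLAT", D = "FLAT")
      n_de <- switch(pat[i], "flat" = 0L, "1-DE" = 1L, "2-DE-same" = 2L,
                     "3-DE-same" = 3L, "opposite" = 2L)
      if (n_de > 0) {
        who <- sample(members, n_de)
        if (pat[i] == "opposite") {
          dirs <- sample(c("UP", "DOWN"))
        } else {
          dirs <- rep(dir_pool[[as.character(i)]], n_de)
        }
        calls[who] <- dirs
        fold[who, i, cn] <- ifelse(dirs == "UP", up_fold, down_fold)
      }
      label_rows[[length(label_rows) + 1]] <- tibble(
        triad_id = triads$triad_id[i], condition = cn, pattern = pat[i],
        call_A = calls[["A"]], call_B = calls[["B"]], call_D = calls[["D"]])
    }
  }

  counts <- matrix(0, nrow = length(gene_ids), ncol = nrow(samples),
                   dimnames = list(gene_ids, samples$sample))
  len_kb <- gene_lengths[gene_ids] / 1000
  for (s in seq_len(nrow(samples))) {
    cn <- samples$condition[s]
    mu <- as.vector(base_level * fold[, , cn]) * len_kb
    counts[, s] <- if (dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    } else {
      round(mu)
    }
  }

  list(
    counts = counts,
    samples = samples,
    gene_lengths = gene_lengths[gene_ids],
    labels = list(
      patterns = bind_rows(label_rows) %>%
        mutate(pattern = ifelse(.data$pattern == "flat", "not-DE", .data$pattern)),
      balance = tibble(triad_id = triads$triad_id,
                       unbalanced = seq_len(n_triads) %in% unbal_idx,
                       dominant = dominant)
    )
  )
}
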