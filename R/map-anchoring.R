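#' Construct a genetic map object
#'
#' A genetic map is a set of markers with categorical centimorgan bin
#' assignments on named chromosomes. Chromosome names must follow the
#' `{group}{subgenome}` convention of hexaploid wheat nomenclature (for
#' example `3B`: homoeologous group 3, subgenome B), from which the
#' homoeology table is derived.
#'
#' @param markers A data frame with columns `marker_id`, `chromosome`,
#'   `cM_bin`.
#' @return An object of class `genetic_map`: list with `markers` (tibble,
#'   `cM_bin` kept as character labels - bins are categorical) and `bins`
#'   (distinct chromosome/cM pairs).
#' @export
genetic_map <- function(markers) {
  markers <- as_tibble(markers)
  need <- c("marker_id", "chromosome", "cM_bin")
  if (!all(need %in% names(markers))) {
    stop("markers must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(markers$marker_id)) stop("marker ids must be unique")
  bad <- unique(markers$chromosome[!grepl("^[0-9]+[A-Z]$", markers$chromosome)])
  if (length(bad)) {
    stop("unknown chromosome name(s) in map: ", paste(bad, collapse = ", "),
         " (expected {group}{subgenome}, e.g. 3B)")
  }
  markers$cM_bin <- as.character(markers$cM_bin)
  out <- list(
    markers = markers[, need],
    bins = distinct(markers[, c("chromosome", "cM_bin")])
  )
  class(out) <- "genetic_map"
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic map: %d markers, %d bins on %d chromosomes\n",
              nrow(x$markers), nrow(x$bins), length(unique(x$bins$chromosome))))
  invisible(x)
}

# group / subgenome parsed from wheat-style chromosome names
chrom_group <- function(chromosome) sub("^([0-9]+)[A-Z]$", "\\1", chromosome)
chrom_subgenome <- function(chromosome) sub("^[0-9]+([A-Z])$", "\\1", chromosome)
# chromosome from an arm label such as 5AL / 5AS
arm_chromosome <- function(arm) sub("^([0-9]+[A-Z])[LS]?$", "\\1", arm)

#' Locate genetic markers on scaffolds by exact matching
#'
#' Reports every exact, full-length match of each marker sequence on either
#' strand of the scaffolds. Markers matching more than `max_hits` distinct
#' scaffolds are considered multi-locus (likely repeats), excluded from the
#' returned hit table, and listed in the `multi_locus` attribute.
#'
#' @param markers Named character vector or `DNAStringSet` of marker
#'   sequences (>= 31 bp each).
#' @param scaffolds Named character vector or `DNAStringSet`.
#' @param max_hits Maximum number of distinct scaffolds a usable marker may
#'   hit (default 2).
#' @return A tibble (`marker_id`, `scaffold_id`, `position`, `strand`) of
#'   usable hits, with attribute `multi_locus` naming the excluded markers.
#' @export
match_markers <- function(markers, scaffolds, max_hits = 2) {
  markers <- as_seq_character(markers, "markers")
  if (any(nchar(markers) < 31)) stop("markers must be at least 31 bp")
  scaffolds <- as_seq_character(scaffolds, "scaffolds")
  subject <- Biostrings::DNAStringSet(scaffolds)
  hit_rows <- vector("list", 2L * length(markers))
  j <- 0L
  for (i in seq_along(markers)) {
    pat <- Biostrings::DNAString(markers[[i]])
    for (str in c("+", "-")) {
      p <- if (str == "+") pat else Biostrings::reverseComplement(pat)
      mi <- Biostrings::vmatchPattern(p, subject)
      st <- Biostrings::startIndex(mi)
      nhit <- lengths(st)
      if (any(nhit > 0)) {
        j <- j + 1L
        hit_rows[[j]] <- tibble(
          marker_id = names(markers)[i],
          scaffold_id = rep(names(scaffolds), nhit),
          position = as.integer(unlist(st[nhit > 0])),
          strand = str
        )
      }
    }
  }
  hits <- if (j > 0) bind_rows(hit_rows[seq_len(j)]) else {
    tibble(marker_id = character(), scaffold_id = character(),
           position = integer(), strand = character())
  }
  per_marker <- hits %>%
    group_by(.data$marker_id) %>%
    summarise(n_scaffolds = dplyr::n_distinct(.data$scaffold_id))
  multi <- per_marker$marker_id[per_marker$n_scaffolds > max_hits]
  if (length(multi)) {
    message(length(multi), " multi-locus marker(s) excluded: ",
            paste(utils::head(multi, 5), collapse = ", "))
  }
  out <- filter(hits, !(.data$marker_id %in% multi))
  attr(out, "multi_locus") <- multi
  out
}

#' Classify one scaffold's map assignment (classes 1-7)
#'
#' Given the map bins of a scaffold's marker hits, assigns the seven-class
#' anchoring verdict:
#' * class 1 - all hits in a single bin of a single chromosome (unique
#'   assignment);
#' * class 2 - hits at different cM positions of the same chromosome;
#' * class 3 - hits on different chromosomes of one homoeologous group;
#' * class 4 - hits on non-homoeologous chromosomes (conflicting bins);
#' * class 5 - a class-1 scaffold with no prior chromosome-arm assignment;
#' * classes 6/7 - a class-1/class-2 scaffold whose prior arm assignment
#'   disagrees with the map chromosome.
#'
#' Classes 5-7 are override tags on the base class: the base class is
#' reported alongside so counts can be aggregated either way.
#'
#' @param hits A data frame of this scaffold's usable marker hits joined to
#'   the map: columns `chromosome`, `cM_bin` (one row per hit).
#' @param prior_arm Optional prior chromosome-arm label (e.g. `"5AL"`) or
#'   `NA`.
#' @return A one-row tibble: `map_class` (character `"1"`..`"7"` or
#'   `"unanchored"`), `base_class`, `chromosome`, `cM_bin`, `n_markers`.
#'   `chromosome`/`cM_bin` are `NA` unless uniquely determined.
#' @export
classify_scaffold <- function(hits, prior_arm = NA) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    return(tibble(map_class = "unanchored", base_class = "unanchored",
                  chromosome = NA_character_, cM_bin = NA_character_,
                  n_markers = 0L))
  }
  chroms <- unique(hits$chromosome)
  bins <- distinct(hits[, c("chromosome", "cM_bin")])
  if (length(chroms) == 1 && nrow(bins) == 1) {
    base <- "1"; chrom <- chroms; bin <- bins$cM_bin[[1]]
  } else if (length(chroms) == 1) {
    base <- "2"; chrom <- chroms; bin <- NA_character_
  } else if (length(unique(chrom_group(chroms))) == 1) {
    base <- "3"; chrom <- NA_character_; bin <- NA_character_
  } else {
    base <- "4"; chrom <- NA_character_; bin <- NA_character_
  }
  cls <- base
  prior_chrom <- if (is.na(prior_arm)) NA_character_ else arm_chromosome(prior_arm)
  if (base == "1" && is.na(prior_chrom)) cls <- "5"
  if (base %in% c("1", "2") && !is.na(prior_chrom) && prior_chrom != chrom) {
    cls <- if (base == "1") "6" else "7"
  }
  tibble(map_class = cls, base_class = base,
         chromosome = chrom, cM_bin = as.character(bin),
         n_markers = nrow(hits))
}

#' Anchor a scaffold assembly to a genetic map
#'
#' Runs marker matching and per-scaffold classification over a whole
#' assembly and reports anchoring summary statistics.
#'
#' @param scaffolds Named character vector or `DNAStringSet`.
#' @param map A `genetic_map`.
#' @param marker_seqs Named character vector or `DNAStringSet` of marker
#'   sequences; names must match `map$markers$marker_id`.
#' @param prior_arms Optional data frame (`scaffold_id`, `arm`) of prior
#'   chromosome-arm assignments.
#' @param hc_genes Optional data frame (`gene_id`, `scaffold_id`) locating
#'   high-confidence genes on scaffolds, used for the gene-space summary.
#' @param max_hits Passed to [match_markers()].
#' @return An object of class `anchor_result`: list with `anchors` (one row
#'   per scaffold: `scaffold_id`, `map_class`, `base_class`, `chromosome`,
#'   `cM_bin`, `n_markers`, `length`) and `summary` (list of per-class
#'   counts and percentages, anchored bp and fraction, and - when
#'   `hc_genes` is given - binned HC-gene counts and fractions).
#' @export
anchor_assembly <- function(scaffolds, map, marker_seqs, prior_arms = NULL,
                            hc_genes = NULL, max_hits = 2) {
  stopifnot(inherits(map, "genetic_map"))
  scaffolds <- as_seq_character(scaffolds, "scaffolds")
  marker_seqs <- as_seq_character(marker_seqs, "marker_seqs")
  unknown <- setdiff(names(marker_seqs), map$markers$marker_id)
  if (length(unknown)) {
    stop("marker sequence(s) not in map: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  hits <- match_markers(marker_seqs, scaffolds, max_hits = max_hits) %>%
    left_join(map$markers, by = "marker_id")
  prior <- if (is.null(prior_arms)) {
    tibble(scaffold_id = character(), arm = character())
  } else as_tibble(prior_arms)
  anchors <- bind_rows(lapply(names(scaffolds), function(sid) {
    sc_hits <- filter(hits, .data$scaffold_id == sid)
    arm <- prior$arm[match(sid, prior$scaffold_id)]
    cbind(tibble(scaffold_id = sid),
          classify_scaffold(sc_hits, prior_arm = if (length(arm)) arm else NA))
  })) %>%
    as_tibble() %>%
    mutate(length = as.integer(nchar(scaffolds[.data$scaffold_id])))

  n_total <- nrow(anchors)
  total_bp <- sum(as.numeric(anchors$length))
  class_levels <- c(as.character(1:7), "unanchored")
  class_counts <- setNames(
    vapply(class_levels, function(cl) sum(anchors$map_class == cl), 0L),
    paste0("class_", class_levels))
  # classes 1 and 5/6 are all uniquely binned (base class 1)
  binned <- anchors$base_class == "1"
  anchored_bp <- sum(as.numeric(anchors$length[binned]))
  summary <- list(
    n_scaffolds = n_total,
    class_counts = class_counts,
    class_pct = pct(class_counts, n_total, digits = 2),
    n_binned = sum(binned),
    binned_pct = pct(sum(binned), n_total, digits = 2),
    anchored_bp = anchored_bp,
    anchored_bp_pct = pct(anchored_bp, total_bp, digits = 2)
  )
  if (!is.null(hc_genes)) {
    hc_genes <- as_tibble(hc_genes)
    gene_scaffolds <- unique(hc_genes$scaffold_id)
    binned_ids <- anchors$scaffold_id[binned]
    genes_binned <- sum(hc_genes$scaffold_id %in% binned_ids)
    summary$n_hc_genes <- nrow(hc_genes)
    summary$hc_genes_binned <- genes_binned
    summary$hc_genes_binned_pct <- pct(genes_binned, nrow(hc_genes), digits = 2)
    summary$hc_scaffolds <- length(gene_scaffolds)
    summary$hc_scaffolds_binned <- sum(gene_scaffolds %in% binned_ids)
    summary$hc_scaffolds_binned_pct <-
      pct(summary$hc_scaffolds_binned, summary$hc_scaffolds, digits = 2)
  }
  out <- list(anchors = anchors, summary = summary)
  class(out) <- "anchor_result"
  out
}

#' @export
print.anchor_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("map anchoring: %d scaffolds\n", s$n_scaffolds))
  for (nm in names(s$class_counts)) {
    cat(sprintf("  %-16s : %6d (%5.2f%%)\n", nm, s$class_counts[[nm]],
                s$class_pct[[nm]]))
  }
  cat(sprintf("  uniquely binned  : %6d (%5.2f%%), %g bp (%5.2f%% of assembly)\n",
              s$n_binned, s$binned_pct, s$anchored_bp, s$anchored_bp_pct))
  invisible(x)
}
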