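#' Compare two gene annotations on a shared coordinate system
#'
#' Categorises every reference gene by its structural relationship to the
#' query annotation (strand-aware; an antisense overlap does not count):
#' * `identical` - some reference transcript shares its complete ordered
#'   exon-intron structure (every intron boundary) with a query transcript;
#' * `contained` - a reference transcript's intron chain occurs as a
#'   contiguous sub-chain of a query transcript's chain, with the reference
#'   span inside the query gene span;
#' * `structurally_different` - same-strand genomic overlap, but neither of
#'   the above;
#' * `missing` - no same-strand overlap with any query gene.
#'
#' Query genes overlapped by two or more distinct reference genes are
#' additionally flagged as candidate fusions (reference models fragmented
#' relative to the query assembly).
#'
#' @param reference,query Exon tables: data frames with one row per exon
#'   and columns `gene_id`, `transcript_id`, `seqid`, `strand`, `start`,
#'   `end`.
#' @return List with `categories` (tibble: `gene_id`, `category`,
#'   `query_gene` of the best match or `NA`), `fractions` (named numeric
#'   over the four categories), and `fusions` (tibble: `query_gene`,
#'   `n_ref_genes`, `ref_genes`).
#' @export
compare_annotations <- function(reference, query) {
  ref <- check_exon_table(reference, "reference")
  qry <- check_exon_table(query, "query")
  ref_genes <- split(ref, ref$gene_id)
  qry_genes <- split(qry, qry$gene_id)
  qry_spans <- lapply(qry_genes, gene_span)

  cat_rows <- lapply(names(ref_genes), function(g) {
    rg <- ref_genes[[g]]
    rspan <- gene_span(rg)
    ov <- names(qry_genes)[vapply(qry_spans, function(qs) {
      qs$seqid == rspan$seqid && qs$strand == rspan$strand &&
        qs$start <= rspan$end && rspan$start <= qs$end
    }, TRUE)]
    if (length(ov) == 0) {
      return(tibble(gene_id = g, category = "missing",
                    query_gene = NA_character_))
    }
    best <- c(category = "structurally_different", query_gene = ov[[1]])
    for (qg in ov) {
      rel <- gene_pair_relation(rg, qry_genes[[qg]], qry_spans[[qg]])
      if (rel == "identical") {
        best <- c(category = "identical", query_gene = qg)
        break
      }
      if (rel == "contained" && best[["category"]] != "identical") {
        best <- c(category = "contained", query_gene = qg)
      }
    }
    tibble(gene_id = g, category = best[["category"]],
           query_gene = best[["query_gene"]])
  })
  categories <- bind_rows(cat_rows)
  lev <- c("identical", "contained", "structurally_different", "missing")
  fractions <- vapply(lev, function(l) mean(categories$category == l), 0)

  ref_spans <- lapply(ref_genes, gene_span)
  fusions <- bind_rows(lapply(names(qry_genes), function(qg) {
    qs <- qry_spans[[qg]]
    hit <- names(ref_genes)[vapply(ref_spans, function(rs) {
      rs$seqid == qs$seqid && rs$strand == qs$strand &&
        rs$start <= qs$end && qs$start <= rs$end
    }, TRUE)]
    if (length(hit) >= 2) {
      tibble(query_gene = qg, n_ref_genes = length(hit),
             ref_genes = paste(sort(hit), collapse = ","))
    } else NULL
  }))
  if (nrow(fusions) == 0) {
    fusions <- tibble(query_gene = character(), n_ref_genes = integer(),
                      ref_genes = character())
  }
  list(categories = categories, fractions = fractions, fusions = fusions)
}

check_exon_table <- function(x, what) {
  x <- as_tibble(x)
  need <- c("gene_id", "transcript_id", "seqid", "strand", "start", "end")
  if (!all(need %in% names(x))) {
    stop(what, " must have columns ", paste(need, collapse = ", "))
  }
  if (any(x$end < x$start) || any(x$start < 1)) {
    stop("malformed coordinates in ", what)
  }
  x
}

gene_span <- function(gene_exons) {
  list(seqid = gene_exons$seqid[[1]], strand = gene_exons$strand[[1]],
       start = min(gene_exons$start), end = max(gene_exons$end))
}

# ordered intron-boundary chain of one transcript's exon rows
exon_rows_chain <- function(ex) {
  ex <- ex[order(ex$start), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2) return(character())
  paste(ex$end[-n] + 1L, ex$start[-1] - 1L, sep = ":")
}

# relation of a reference gene to one query gene: identical / contained /
# structurally_different (overlap is already established by the caller)
gene_pair_relation <- function(ref_gene, qry_gene, qry_span) {
  ref_txs <- split(ref_gene, ref_gene$transcript_id)
  qry_txs <- split(qry_gene, qry_gene$transcript_id)
  rspan <- gene_span(ref_gene)
  inside <- qry_span$start <= rspan$start && rspan$end <= qry_span$end
  best <- "structurally_different"
  for (rt in ref_txs) {
    rc <- exon_rows_chain(rt)
    for (qt in qry_txs) {
      qc <- exon_rows_chain(qt)
      if (length(rc) == length(qc) && all(rc == qc)) return("identical")
      if (inside && is_contiguous_subchain(rc, qc)) best <- "contained"
    }
  }
  best
}

is_contiguous_subchain <- function(sub, chain) {
  ns <- length(sub)
  nc <- length(chain)
  if (ns > nc) return(FALSE)
  if (ns == 0) return(TRUE)  # monoexonic chain is trivially contained
  for (off in 0:(nc - ns)) {
    if (all(chain[off + seq_len(ns)] == sub)) return(TRUE)
  }
  FALSE
}
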