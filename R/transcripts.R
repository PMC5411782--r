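#' Construct a transcript model
#'
#' A transcript is an ordered set of exons on one strand of one sequence,
#' optionally with CDS segments. Coordinates are 1-based inclusive (GFF3
#' convention). Exons must be non-overlapping; they are stored sorted by
#' genomic start, with mRNA order derived from the strand.
#'
#' @param exons Data frame or matrix with columns `start`, `end`.
#' @param strand `"+"` or `"-"`.
#' @param cds Optional data frame with columns `start`, `end`; every CDS
#'   segment must lie within an exon.
#' @param id Transcript identifier.
#' @param seqid Sequence (chromosome/scaffold) name.
#' @return An object of class `transcript`.
#' @export
transcript <- function(exons, strand = "+", cds = NULL, id = "tx1",
                       seqid = "seq1") {
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (nrow(exons) == 0) stop("transcript needs at least one exon")
  if (any(exons$end < exons$start)) stop("malformed exon coordinates")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons overlap or abut without an intron")
  }
  if (!is.null(cds)) {
    cds <- as.data.frame(cds)[, c("start", "end")]
    cds <- cds[order(cds$start), , drop = FALSE]
    rownames(cds) <- NULL
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    }, TRUE)
    if (!all(inside)) stop("CDS segments must lie within exons")
  }
  structure(list(id = id, seqid = seqid, strand = strand,
                 exons = exons, cds = cds),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript %s (%s:%s, %d exon(s)%s)\n", x$id, x$seqid,
              x$strand, nrow(x$exons),
              if (is.null(x$cds)) "" else sprintf(", %d CDS segment(s)", nrow(x$cds))))
  invisible(x)
}

# introns as a data.frame(start, end) in genomic coordinates (sorted)
tx_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

# total exonic length
tx_length <- function(tx) sum(tx$exons$end - tx$exons$start + 1L)

# genomic position -> 1-based mRNA coordinate (must fall inside an exon)
genomic_to_mrna <- function(tx, pos) {
  ex <- tx$exons
  widths <- ex$end - ex$start + 1L
  i <- which(ex$start <= pos & pos <= ex$end)
  if (length(i) != 1) stop("position ", pos, " not in an exon of ", tx$id)
  if (tx$strand == "+") {
    sum(widths[seq_len(i - 1)]) + (pos - ex$start[i] + 1L)
  } else {
    n <- nrow(ex)
    sum(widths[seq(i + 1, length.out = n - i)]) + (ex$end[i] - pos + 1L)
  }
}

#' Flag a transcript as a candidate nonsense-mediated-decay target
#'
#' Applies the 50-nt rule: a transcript is a candidate NMD substrate when
#' its stop codon lies more than `distance` nucleotides upstream of the
#' final exon-exon junction in mRNA coordinates. Monoexonic transcripts
#' have no junction and are never flagged; transcripts without a CDS are
#' not evaluable and return `FALSE` with a message.
#'
#' @param tx A [transcript()] with CDS segments.
#' @param distance Minimum stop-to-last-junction distance in nt that
#'   triggers the flag (default 50; the comparison is strict).
#' @return Logical scalar.
#' @export
flag_nmd <- function(tx, distance = 50) {
  stopifnot(inherits(tx, "transcript"))
  if (is.null(tx$cds) || nrow(tx$cds) == 0) {
    message("transcript ", tx$id, " has no CDS; NMD not evaluable")
    return(FALSE)
  }
  if (nrow(tx$exons) < 2) return(FALSE)
  stop_genomic <- if (tx$strand == "+") max(tx$cds$end) else min(tx$cds$start)
  stop_pos <- genomic_to_mrna(tx, stop_genomic)
  widths <- tx$exons$end - tx$exons$start + 1L
  # last junction = end of the penultimate exon in mRNA orientation
  last_junction <- if (tx$strand == "+") {
    sum(widths[-length(widths)])
  } else {
    sum(widths[-1])
  }
  (last_junction - stop_pos) > distance
}
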