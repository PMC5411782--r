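#' Classify alternative-splicing events between transcript isoforms
#'
#' Compares each alternative transcript of a gene against the
#' representative isoform and types the local differences between their
#' intron chains:
#' * `IR` - intron retention: an exon of one isoform fully spans an intron
#'   of the other;
#' * `ES` - exon skipping: an internal exon of one isoform is absent from
#'   the other while the outer boundaries of the two flanking introns are
#'   shared (the other isoform has the single merged intron);
#' * `MXE` - mutually exclusive exons: two non-overlapping internal exons,
#'   each present in exactly one isoform, framed by introns with shared
#'   outer boundaries;
#' * `A5SS` / `A3SS` - a shared intron boundary with the donor
#'   (respectively acceptor) shifted, assigned in mRNA orientation: on the
#'   minus strand the genomic-left intron boundary is the acceptor.
#'
#' One transcript pair may yield several events. A transcript compared
#' with itself yields none.
#'
#' @param transcripts List of [transcript()] objects of one gene, sharing
#'   `seqid` and `strand`.
#' @param representative Id of the reference isoform; defaults to the
#'   first transcript.
#' @return Tibble: `ref_id`, `alt_id`, `event`.
#' @export
classify_as_events <- function(transcripts, representative = NULL) {
  if (inherits(transcripts, "transcript")) transcripts <- list(transcripts)
  stopifnot(all(vapply(transcripts, inherits, TRUE, "transcript")))
  empty <- tibble(ref_id = character(), alt_id = character(),
                  event = character())
  if (length(transcripts) < 2) return(empty)
  ids <- vapply(transcripts, `[[`, "", "id")
  if (is.null(representative)) representative <- ids[[1]]
  if (!representative %in% ids) stop("representative transcript not found")
  if (length(unique(vapply(transcripts, `[[`, "", "strand"))) != 1 ||
      length(unique(vapply(transcripts, `[[`, "", "seqid"))) != 1) {
    stop("all transcripts of a gene must share seqid and strand")
  }
  ref <- transcripts[[match(representative, ids)]]
  out <- lapply(transcripts[ids != representative], function(alt) {
    ev <- pairwise_as_events(ref, alt)
    if (length(ev)) tibble(ref_id = ref$id, alt_id = alt$id, event = ev) else NULL
  })
  bind_rows(c(list(empty), out))
}

intron_key <- function(introns) {
  if (nrow(introns) == 0) return(character())
  paste(introns$start, introns$end, sep = ":")
}

# All events between one pair of isoforms; returns a character vector.
# Detection order matters: IR, ES and MXE structures are recognised first
# and their introns marked as explained, so a shifted-looking boundary that
# is really part of a skipped or mutually exclusive exon is not double
# reported as A5SS/A3SS.
pairwise_as_events <- function(a, b) {
  ia <- tx_introns(a)
  ib <- tx_introns(b)
  ka <- intron_key(ia)
  kb <- intron_key(ib)
  used_a <- logical(nrow(ia))
  used_b <- logical(nrow(ib))
  events <- character()

  # intron retention: exon of one spans an intron of the other
  spans <- function(exons, s, e) any(exons$start < s & exons$end > e)
  for (i in seq_len(nrow(ia))) {
    if (!ka[i] %in% kb && spans(b$exons, ia$start[i], ia$end[i])) {
      events <- c(events, "IR"); used_a[i] <- TRUE
    }
  }
  for (j in seq_len(nrow(ib))) {
    if (!kb[j] %in% ka && spans(a$exons, ib$start[j], ib$end[j])) {
      events <- c(events, "IR"); used_b[j] <- TRUE
    }
  }

  # exon skipping: consecutive introns of one = single merged intron of other
  check_es <- function(ix, kx, used_x, iy, ky, used_y) {
    for (i in seq_len(nrow(ix) - 1L)) {
      if (used_x[i] || used_x[i + 1]) next
      merged <- paste(ix$start[i], ix$end[i + 1], sep = ":")
      j <- match(merged, ky)
      if (!is.na(j) && !used_y[j]) {
        events <<- c(events, "ES")
        used_x[i] <- used_x[i + 1] <- TRUE
        used_y[j] <- TRUE
      }
    }
    list(used_x, used_y)
  }
  if (nrow(ia) >= 2) {
    r <- check_es(ia, ka, used_a, ib, kb, used_b); used_a <- r[[1]]; used_b <- r[[2]]
  }
  if (nrow(ib) >= 2) {
    r <- check_es(ib, kb, used_b, ia, ka, used_a); used_b <- r[[1]]; used_a <- r[[2]]
  }

  # mutually exclusive exons: intron pairs share outer boundaries, internal
  # exons disjoint
  if (nrow(ia) >= 2 && nrow(ib) >= 2) {
    for (i in seq_len(nrow(ia) - 1L)) {
      if (used_a[i] || used_a[i + 1]) next
      for (j in seq_len(nrow(ib) - 1L)) {
        if (used_b[j] || used_b[j + 1]) next
        if (ia$start[i] == ib$start[j] && ia$end[i + 1] == ib$end[j + 1]) {
          ex_a <- c(ia$end[i] + 1L, ia$start[i + 1] - 1L)
          ex_b <- c(ib$end[j] + 1L, ib$start[j + 1] - 1L)
          distinct_exons <- !(ex_a[1] == ex_b[1] && ex_a[2] == ex_b[2])
          disjoint <- ex_a[2] < ex_b[1] || ex_b[2] < ex_a[1]
          if (distinct_exons && disjoint) {
            events <- c(events, "MXE")
            used_a[i] <- used_a[i + 1] <- TRUE
            used_b[j] <- used_b[j + 1] <- TRUE
          }
        }
      }
    }
  }

  # alternative donor/acceptor on the remaining unexplained introns
  for (i in seq_len(nrow(ia))) {
    if (used_a[i] || ka[i] %in% kb) next
    for (j in seq_len(nrow(ib))) {
      if (used_b[j] || kb[j] %in% ka) next
      same_start <- ia$start[i] == ib$start[j]
      same_end <- ia$end[i] == ib$end[j]
      if (xor(same_start, same_end)) {
        right_shift <- same_start  # genomic-right boundary differs
        ev <- if (a$strand == "+") {
          if (right_shift) "A3SS" else "A5SS"
        } else {
          if (right_shift) "A5SS" else "A3SS"
        }
        events <- c(events, ev)
        used_a[i] <- TRUE
        used_b[j] <- TRUE
        break
      }
    }
  }
  events
}
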