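#' Assemble S1-S4 voltage-sensing-domain candidates
#'
#' Combines S2 motif hits with predicted transmembrane helices into
#' four-helix architecture calls. A motif hit whose full 8-residue span
#' lies inside a predicted helix nominates that helix as S2; the
#' nearest preceding helix becomes S1 and the two nearest following
#' helices become S3 and S4. A call is emitted only when every
#' inter-helix loop is at most `max_loop` residues and the S1-start to
#' S4-end span is at most `max_span` residues — voltage-sensing domains
#' are compact four-helix bundles, and the bounds stop the caller from
#' chaining helices across unrelated domains.
#'
#' @param record A single-row [protein_records] data frame (or a list
#'   with `id` and `sequence`).
#' @param helices Data frame of helices as returned by
#'   [predict_tm_helices()], sorted and non-overlapping.
#' @param hits Data frame of motif hits as returned by [scan_motif()]
#'   for the same record.
#' @param max_candidates Emit at most this many candidates (default
#'   100).
#' @param max_loop Maximum loop length between consecutive helices of
#'   one candidate (residues, default 80).
#' @param max_span Maximum S1-start to S4-end extent (residues, default
#'   300).
#' @return A data frame with one row per candidate, sorted by
#'   `anchor_pos`, with columns `record_id`, `s1_start`, `s1_end`, ...,
#'   `s4_start`, `s4_end`, `anchor_pos`, `acidic_pos`, `basic_pos`,
#'   `vsd_start`, `vsd_end`, `s4_sequence`. A record with no valid
#'   architecture yields zero rows.
#' @examples
#' rec <- protein_records("p1", paste0(
#'   strrep("G", 20), strrep("L", 20), strrep("G", 10),
#'   "LLLLLLFLLDLLLRLLLLLL", strrep("G", 10), strrep("L", 20),
#'   strrep("G", 10), strrep("L", 20), strrep("G", 20)))
#' h <- tm_helices(rec$sequence)
#' m <- scan_motif(rec$sequence, "strict")
#' assemble_vsd(rec, h, m)
#' @export
assemble_vsd <- function(record, helices, hits, max_candidates = 100L,
                         max_loop = 80L, max_span = 300L) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  empty <- data.frame(
    record_id = character(0),
    s1_start = integer(0), s1_end = integer(0),
    s2_start = integer(0), s2_end = integer(0),
    s3_start = integer(0), s3_end = integer(0),
    s4_start = integer(0), s4_end = integer(0),
    anchor_pos = integer(0), acidic_pos = integer(0),
    basic_pos = integer(0),
    vsd_start = integer(0), vsd_end = integer(0),
    s4_sequence = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L || nrow(helices) < 4L) return(empty)
  helices <- helices[order(helices$start), , drop = FALSE]
  out <- vector("list", nrow(hits))
  for (k in seq_len(nrow(hits))) {
    a <- hits$anchor_pos[k]
    span_end <- a + 7L
    s2_idx <- which(helices$start <= a & helices$end >= span_end)
    if (length(s2_idx) == 0L) next
    s2_idx <- s2_idx[1L]
    prev_idx <- which(helices$end < helices$start[s2_idx])
    next_idx <- which(helices$start > helices$end[s2_idx])
    if (length(prev_idx) < 1L || length(next_idx) < 2L) next
    s1_idx <- max(prev_idx)               # nearest preceding
    s3_idx <- next_idx[1L]                # two nearest following
    s4_idx <- next_idx[2L]
    loop12 <- helices$start[s2_idx] - helices$end[s1_idx] - 1L
    loop23 <- helices$start[s3_idx] - helices$end[s2_idx] - 1L
    loop34 <- helices$start[s4_idx] - helices$end[s3_idx] - 1L
    span <- helices$end[s4_idx] - helices$start[s1_idx] + 1L
    if (loop12 > max_loop || loop23 > max_loop || loop34 > max_loop ||
        span > max_span) next
    out[[k]] <- data.frame(
      record_id = record$id,
      s1_start = helices$start[s1_idx], s1_end = helices$end[s1_idx],
      s2_start = helices$start[s2_idx], s2_end = helices$end[s2_idx],
      s3_start = helices$start[s3_idx], s3_end = helices$end[s3_idx],
      s4_start = helices$start[s4_idx], s4_end = helices$end[s4_idx],
      anchor_pos = a, acidic_pos = hits$acidic_pos[k],
      basic_pos = hits$basic_pos[k],
      vsd_start = helices$start[s1_idx], vsd_end = helices$end[s4_idx],
      s4_sequence = substring(record$sequence, helices$start[s4_idx],
                              helices$end[s4_idx]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$anchor_pos), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_candidates)
}
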