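#' Scan a protein sequence for the conserved S2 anchor motif
#'
#' The voltage-sensing-domain S2 helix carries a conserved architecture:
#' a bulky hydrophobic anchor residue, an acidic residue three positions
#' downstream and a basic residue seven positions downstream — the
#' pattern `Fxx[E,D]xxx[R,K]` where `x` is any residue. In `strict` mode
#' the anchor must be phenylalanine; `relaxed` mode broadens the anchor
#' to `[F,Y,W]`, which extends the reach of the search (e.g. to plant
#' voltage sensors). All overlapping occurrences are reported; `X` never
#' satisfies a motif slot.
#'
#' @param seq Amino-acid string over the package alphabet
#'   ([AA_ALPHABET_X]). May be shorter than 8 residues, in which case no
#'   hit is possible.
#' @param mode `"strict"` (anchor F) or `"relaxed"` (anchor F/Y/W).
#' @return A data frame with one row per hit, sorted by `anchor_pos`:
#'   \describe{
#'     \item{anchor_pos, anchor_res}{1-based position and residue of the
#'       hydrophobic anchor.}
#'     \item{acidic_pos, acidic_res}{`anchor_pos + 3` and the D/E found
#'       there.}
#'     \item{basic_pos, basic_res}{`anchor_pos + 7` and the R/K found
#'       there.}
#'     \item{mode}{the scan mode used.}
#'     \item{matched_span}{the 8-residue matched substring.}
#'   }
#' @examples
#' scan_motif("FAADAAAR", "strict")     # one hit at anchor 1
#' scan_motif("YAAEAAAK", "relaxed")    # Y anchor, relaxed only
#' @export
scan_motif <- function(seq, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  validate_sequence(seq)
  anchor_class <- if (mode == "strict") "[F]" else "[FYW]"
  # wildcard slots admit the 20 canonical residues but not masked X
  x_class <- "[ARNDCQEGHILKMFPSTWYV]"
  # zero-width lookahead so overlapping occurrences are all found
  pattern <- paste0("(?=", anchor_class, x_class, "{2}[DE]",
                    x_class, "{3}[RK])")
  m <- gregexpr(pattern, seq, perl = TRUE)[[1L]]
  pos <- as.integer(m)
  pos <- pos[pos > 0L]
  empty_hits <- function() {
    data.frame(anchor_pos = integer(0), anchor_res = character(0),
               acidic_pos = integer(0), acidic_res = character(0),
               basic_pos = integer(0), basic_res = character(0),
               mode = character(0), matched_span = character(0),
               stringsAsFactors = FALSE)
  }
  if (length(pos) == 0L) return(empty_hits())
  data.frame(
    anchor_pos = pos,
    anchor_res = substring(seq, pos, pos),
    acidic_pos = pos + 3L,
    acidic_res = substring(seq, pos + 3L, pos + 3L),
    basic_pos = pos + 7L,
    basic_res = substring(seq, pos + 7L, pos + 7L),
    mode = mode,
    matched_span = substring(seq, pos, pos + 7L),
    stringsAsFactors = FALSE
  )
}

#' Scan a collection of protein records for the S2 anchor motif
#'
#' @param records A [protein_records] data frame.
#' @inheritParams scan_motif
#' @return A data frame as in [scan_motif()] with an additional leading
#'   `id` column; records without hits contribute no rows.
#' @export
scan_records <- function(records, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(nrow(records)), function(k) {
    hits <- scan_motif(records$sequence[k], mode)
    if (nrow(hits) == 0L) return(NULL)
    cbind(id = records$id[k], hits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(id = character(0), scan_motif("AAAAAAAA", mode))
  }
  rownames(out) <- NULL
  out
}
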