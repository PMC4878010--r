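#' Define a scaffold sensor
#'
#' A scaffold GEVI is described by its full protein sequence and three
#' contiguous spans that partition it exactly: the cytoplasmic
#' N-terminus, the four-helix VSD, and the linker plus fluorescent
#' protein. Chimera design keeps the N-terminus and linker+FP and swaps
#' the VSD.
#'
#' @param name Scaffold name.
#' @param sequence Full protein sequence.
#' @param nterm_span,vsd_span,linker_fp_span Length-2 integer vectors
#'   of 1-based inclusive spans, in order, jointly covering the
#'   sequence with no gaps or overlaps.
#' @return An object of class `scaffold_sensor`.
#' @export
scaffold_sensor <- function(name, sequence, nterm_span, vsd_span,
                            linker_fp_span) {
  sequence <- toupper(sequence)
  validate_sequence(sequence, name)
  spans <- list(nterm = as.integer(nterm_span),
                vsd = as.integer(vsd_span),
                linker_fp = as.integer(linker_fp_span))
  L <- nchar(sequence)
  for (nm in names(spans)) {
    s <- spans[[nm]]
    if (length(s) != 2L || s[1L] > s[2L]) {
      stop("malformed ", nm, " span")
    }
  }
  if (spans$nterm[1L] != 1L ||
      spans$vsd[1L] != spans$nterm[2L] + 1L ||
      spans$linker_fp[1L] != spans$vsd[2L] + 1L ||
      spans$linker_fp[2L] != L) {
    stop("spans must partition the sequence contiguously: nterm, vsd, ",
         "linker_fp")
  }
  structure(list(name = name, sequence = sequence,
                 nterm_span = spans$nterm, vsd_span = spans$vsd,
                 linker_fp_span = spans$linker_fp),
            class = "scaffold_sensor")
}

#' Read a scaffold sensor definition from a JSON config file
#'
#' Expected fields: `name`, `sequence`, `nterm_span`, `vsd_span`,
#' `linker_fp_span` (each span a two-element array).
#'
#' @param path Path to a JSON file.
#' @return A [scaffold_sensor] object.
#' @export
read_scaffold <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaffold_sensor(cfg$name, cfg$sequence, cfg$nterm_span, cfg$vsd_span,
                  cfg$linker_fp_span)
}

#' Build a chimeric GEVI by swapping a donor VSD into a scaffold
#'
#' The product is the verbatim concatenation scaffold N-terminus ++
#' donor S1-S4 span ++ scaffold linker+FP. Assembly is protein-level
#' only; no DNA is produced.
#'
#' @param scaffold A [scaffold_sensor].
#' @param donor A single candidate row as returned by [assemble_vsd()]
#'   (uses `record_id`, `vsd_start`, `vsd_end`), or any list with those
#'   fields.
#' @param donor_record The donor [protein_records] row (or list with
#'   `id`, `sequence`) the candidate was called on.
#' @return An object of class `chimera_design` with fields
#'   `scaffold_name`, `donor_id`, `sequence` and `part_map` (a data
#'   frame of part label, source, and span in the product).
#' @export
build_chimera <- function(scaffold, donor, donor_record) {
  stopifnot(inherits(scaffold, "scaffold_sensor"))
  if (is.data.frame(donor)) {
    stopifnot(nrow(donor) == 1L)
    donor <- as.list(donor)
  }
  if (is.data.frame(donor_record)) {
    stopifnot(nrow(donor_record) == 1L)
    donor_record <- as.list(donor_record)
  }
  if (!identical(as.character(donor$record_id),
                 as.character(donor_record$id))) {
    stop("candidate record_id does not match donor record id")
  }
  L <- nchar(donor_record$sequence)
  if (donor$vsd_start < 1L || donor$vsd_end > L ||
      donor$vsd_start > donor$vsd_end) {
    stop("donor VSD span exceeds donor sequence")
  }
  nterm <- substring(scaffold$sequence, scaffold$nterm_span[1L],
                     scaffold$nterm_span[2L])
  linker_fp <- substring(scaffold$sequence, scaffold$linker_fp_span[1L],
                         scaffold$linker_fp_span[2L])
  donor_vsd <- substring(donor_record$sequence, donor$vsd_start,
                         donor$vsd_end)
  product <- paste0(nterm, donor_vsd, linker_fp)
  n1 <- nchar(nterm); n2 <- nchar(donor_vsd); n3 <- nchar(linker_fp)
  part_map <- data.frame(
    part = c("nterm", "vsd", "linker_fp"),
    source = c(scaffold$name, as.character(donor$record_id),
               scaffold$name),
    start = c(1L, n1 + 1L, n1 + n2 + 1L),
    end = c(n1, n1 + n2, n1 + n2 + n3),
    stringsAsFactors = FALSE)
  structure(list(scaffold_name = scaffold$name,
                 donor_id = as.character(donor$record_id),
                 sequence = product, part_map = part_map),
            class = "chimera_design")
}

#' @export
print.chimera_design <- function(x, ...) {
  cat("Chimera:", x$scaffold_name, "VSD <-", x$donor_id,
      "| product length", nchar(x$sequence), "\n")
  print(x$part_map)
  invisible(x)
}

#' Annotate the cloning cassette of a chimera design
#'
#' Records, at the protein level, that the swapped VSD segment
#' corresponds to the BamHI/EcoRV restriction cassette of the cloning
#' scheme used to assemble such constructs. No DNA is emitted.
#'
#' @param design A [chimera_design].
#' @return A single annotation string naming both restriction sites and
#'   the product span of the swapped segment, with attribute `span`.
#' @export
flank_for_cloning <- function(design) {
  stopifnot(inherits(design, "chimera_design"))
  vsd_row <- design$part_map[design$part_map$part == "vsd", ]
  note <- sprintf(
    paste0("Swapped VSD cassette (donor %s) occupies product residues ",
           "%d-%d; at the DNA level this segment is the ",
           "BamHI/EcoRV cassette of the cloning scheme."),
    design$donor_id, vsd_row$start, vsd_row$end)
  attr(note, "span") <- c(vsd_row$start, vsd_row$end)
  note
}
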