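#' Amino-acid alphabet used throughout the package
#'
#' The 20 canonical residues plus `X` for unknown/masked positions. `X`
#' never satisfies a motif slot or a template slot and contributes a
#' neutral hydropathy of 0.
#'
#' @format A character vector of length 21.
#' @export
AA_ALPHABET_X <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Construct a collection of protein records
#'
#' A `protein_records` object is a data frame with columns `id`,
#' `description` and `sequence`. Sequences are uppercased and validated
#' against the package alphabet ([AA_ALPHABET_X]); ids must be unique.
#'
#' @param id Character vector of accession-like identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param description Optional character vector of free-text descriptions.
#' @return A data frame of class `protein_records`.
#' @examples
#' protein_records(c("a", "b"), c("MFK", "RRR"))
#' @export
protein_records <- function(id, sequence, description = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (is.null(description)) description <- rep("", length(id))
  description <- as.character(description)
  stopifnot(length(id) == length(sequence),
            length(id) == length(description))
  dup <- id[duplicated(id)]
  if (length(dup) > 0L) {
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  }
  for (k in seq_along(id)) {
    validate_sequence(sequence[k], id[k])
  }
  structure(
    data.frame(id = id, description = description, sequence = sequence,
               stringsAsFactors = FALSE),
    class = c("protein_records", "data.frame")
  )
}

# Error if seq is empty or holds a character outside the alphabet; the
# message names the offending character, its position and the record.
validate_sequence <- function(seq, id = "<unnamed>") {
  if (is.na(seq) || nchar(seq) == 0L) {
    stop("record '", id, "' has an empty sequence")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALPHABET_X))
  if (length(bad) > 0L) {
    stop("illegal character '", chars[bad[1L]], "' at position ", bad[1L],
         " of record '", id, "'")
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-record) protein FASTA file. Sequences are uppercased;
#' gap characters (`-`, `.`) and whitespace are stripped before
#' validation, so alignment-style input is tolerated. The first
#' whitespace-delimited token of each header becomes the record id, the
#' remainder the description. Duplicate ids and characters outside the
#' package alphabet are errors.
#'
#' @param path Path to a FASTA file.
#' @return A [protein_records] data frame, one row per FASTA record, in
#'   file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  if (length(set) == 0L) {
    return(protein_records(character(0), character(0), character(0)))
  }
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- gsub("[-.[:space:]]", "", seqs)
  names(seqs) <- NULL
  protein_records(id, seqs, description)
}

#' Write protein records to a FASTA file
#'
#' Output is wrapped at a fixed line width; wrapping never changes
#' content, and `read_fasta(write_fasta(x))` reproduces ids,
#' descriptions and sequences exactly.
#'
#' @param records A [protein_records] data frame.
#' @param path Output file path.
#' @param width Line-wrap width in residues (default 60).
#' @return The output path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), width >= 1L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    header <- if (nzchar(records$description[k])) {
      paste(records$id[k], records$description[k])
    } else {
      records$id[k]
    }
    writeLines(paste0(">", header), con)
    seq <- records$sequence[k]
    starts <- seq.int(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))),
               con)
  }
  invisible(path)
}
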