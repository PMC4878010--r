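#' Construct an S4 family template
#'
#' A template is an ordered list of slots describing the periodicity of
#' charged residues along the S4 helix. Slot codes:
#' \describe{
#'   \item{`basic`}{R or K.}
#'   \item{`R`}{arginine only.}
#'   \item{`RH`}{R or H (the VSP terminal slot).}
#'   \item{`I`}{isoleucine only.}
#'   \item{`x`}{any canonical residue (not X).}
#' }
#'
#' @param name Family label, e.g. `"Hv"`.
#' @param slots Character vector of slot codes, length >= 7.
#' @param source `"builtin"` or `"user"`.
#' @return An object of class `s4_template`.
#' @export
s4_template <- function(name, slots, source = "user") {
  slots <- as.character(slots)
  allowed <- c("basic", "R", "RH", "I", "x")
  bad <- setdiff(unique(slots), allowed)
  if (length(bad) > 0L) {
    stop("unknown slot code(s): ", paste(bad, collapse = ", "))
  }
  if (length(slots) < 7L) stop("template must have >= 7 slots")
  structure(list(name = name, slots = slots, source = source),
            class = "s4_template")
}

#' @export
print.s4_template <- function(x, ...) {
  cat("S4 template", x$name, "(", x$source, "):",
      paste(x$slots, collapse = "-"), "\n")
  invisible(x)
}

#' Built-in S4 family templates
#'
#' The two families whose S4 consensus is textually established:
#' the proton-channel family Hv, `R-x-x-R-x-x-R`, and the
#' voltage-sensing phosphatase family VSP,
#' `R-x-x-R-x-x-I-x-x-R-x-x-(R/H)`. Basic slots admit R or K (mirroring
#' the R/K equivalence of the S2 motif) unless `strict_arg = TRUE`,
#' which restores arginine-only matching; the VSP terminal slot admits
#' R or H in either case.
#'
#' @param strict_arg If `TRUE`, basic slots match R only.
#' @return A named list of [s4_template] objects (`Hv`, `VSP`).
#' @export
builtin_s4_templates <- function(strict_arg = FALSE) {
  b <- if (strict_arg) "R" else "basic"
  list(
    Hv = s4_template("Hv", c(b, "x", "x", b, "x", "x", b),
                     source = "builtin"),
    VSP = s4_template("VSP", c(b, "x", "x", b, "x", "x", "I",
                               "x", "x", b, "x", "x", "RH"),
                      source = "builtin")
  )
}

#' Fingerprint the basic-residue periodicity of an S4 helix
#'
#' Records the 1-based positions of R and K within the sequence, the
#' successive spacings between them, and their count. Histidine is only
#' partially charged at physiological pH and is excluded from the
#' fingerprint (template slots that explicitly admit H are handled in
#' [classify_s4()]).
#'
#' @param s4_seq Non-empty amino-acid string (an extracted S4 helix).
#' @return A list of class `s4_fingerprint` with `basic_positions`,
#'   `spacing_vector` and `basic_count`.
#' @examples
#' fingerprint_s4("RLLRLLRLL")  # positions 1,4,7; spacings 3,3
#' @export
fingerprint_s4 <- function(s4_seq) {
  stopifnot(length(s4_seq) == 1L)
  s4_seq <- toupper(s4_seq)
  validate_sequence(s4_seq)
  chars <- strsplit(s4_seq, "", fixed = TRUE)[[1L]]
  pos <- which(chars %in% c("R", "K"))
  structure(list(basic_positions = pos,
                 spacing_vector = if (length(pos) > 1L) diff(pos)
                                  else integer(0),
                 basic_count = length(pos)),
            class = "s4_fingerprint")
}

# Does template tpl match s4 chars contiguously starting at offset?
slot_matches <- function(chars, slots, offset) {
  for (j in seq_along(slots)) {
    ch <- chars[offset + j - 1L]
    ok <- switch(slots[j],
                 basic = ch %in% c("R", "K"),
                 R = ch == "R",
                 RH = ch %in% c("R", "H"),
                 I = ch == "I",
                 x = ch != "X")
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Classify an S4 helix against voltage-sensor family templates
#'
#' A template matches when its slot list is satisfied contiguously at
#' some offset of the sequence. All matches are collected; the label is
#' taken from the matched template with the longest pattern (longer
#' patterns constrain more positions, so length stands in for
#' specificity), ties broken by template declaration order. With no
#' match the label is `"unclassified"`.
#'
#' @param s4_seq Amino-acid string of an S4 helix.
#' @param templates List of [s4_template] objects; defaults to
#'   [builtin_s4_templates()].
#' @return A list of class `family_call`: `label`, `matched_template`
#'   (an [s4_template] or `NULL`), `match_offset` (1-based, or `NA`),
#'   and `all_matches` (data frame of template/offset/length).
#' @examples
#' classify_s4("RLLRLLRLL")$label        # "Hv"
#' classify_s4("RLLRLLILLRLLR")$label    # "VSP"
#' @export
classify_s4 <- function(s4_seq, templates = builtin_s4_templates()) {
  stopifnot(length(templates) >= 1L)
  s4_seq <- toupper(s4_seq)
  validate_sequence(s4_seq)
  chars <- strsplit(s4_seq, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (t in seq_along(templates)) {
    tpl <- templates[[t]]
    w <- length(tpl$slots)
    if (w > length(chars)) next
    for (off in seq_len(length(chars) - w + 1L)) {
      if (slot_matches(chars, tpl$slots, off)) {
        rows[[length(rows) + 1L]] <-
          data.frame(template = tpl$name, offset = off,
                     length = w, template_index = t,
                     stringsAsFactors = FALSE)
      }
    }
  }
  all_matches <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(template = character(0), offset = integer(0),
               length = integer(0), template_index = integer(0),
               stringsAsFactors = FALSE)
  if (nrow(all_matches) == 0L) {
    return(structure(list(label = "unclassified", matched_template = NULL,
                          match_offset = NA_integer_,
                          all_matches = all_matches),
                     class = "family_call"))
  }
  # longest template wins; ties by declaration order, then first offset
  best <- all_matches[order(-all_matches$length,
                            all_matches$template_index,
                            all_matches$offset), ][1L, ]
  structure(list(label = best$template,
                 matched_template = templates[[best$template_index]],
                 match_offset = best$offset,
                 all_matches = all_matches),
            class = "family_call")
}

#' @export
print.family_call <- function(x, ...) {
  cat("S4 family call:", x$label,
      if (!is.na(x$match_offset)) paste0("(offset ", x$match_offset, ")"),
      "\n")
  invisible(x)
}

#' Read user S4 templates from a slot-list text file
#'
#' One template per non-comment line: `name: slot-slot-...`, e.g.
#' `Kv: basic-x-x-basic-x-x-basic-x-x-basic`. Slot codes as in
#' [s4_template()]. Lines starting with `#` are ignored.
#'
#' @param path Path to a template file.
#' @return A named list of [s4_template] objects with source `"user"`.
#' @export
read_s4_templates <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed template line: ", ln)
    name <- trimws(parts[1L])
    slots <- strsplit(trimws(parts[2L]), "-", fixed = TRUE)[[1L]]
    out[[name]] <- s4_template(name, trimws(slots), source = "user")
  }
  out
}
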