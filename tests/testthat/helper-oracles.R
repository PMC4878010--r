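# Independent oracles and small random-input generators shared across
# the suite. These deliberately use different algorithmic routes than
# the implementation they check.

AA20_TEST <- setdiff(AA_ALPHABET_X, "X")

# uniformly random protein sequences; x_rate > 0 sprinkles masked X
random_seq <- function(len, x_rate = 0) {
  chars <- sample(AA20_TEST, len, replace = TRUE)
  if (x_rate > 0) {
    mask <- runif(len) < x_rate
    chars[mask] <- "X"
  }
  paste(chars, collapse = "")
}

random_records <- function(n, len_range = c(5L, 60L), prefix = "r") {
  lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  protein_records(
    id = paste0(prefix, seq_len(n)),
    sequence = vapply(lens, random_seq, character(1)),
    description = ifelse(seq_len(n) %% 2L == 0L,
                         paste("random protein", seq_len(n)), ""))
}

# Per-position brute-force check of the S2 anchor motif: examines every
# start index with explicit character comparisons (short-circuited so
# the loop stays fast at scale).
oracle_motif_positions <- function(seq, mode) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 8L) return(integer(0))
  relaxed <- mode == "relaxed"
  hits <- integer(0)
  for (i in seq_len(L - 7L)) {
    a <- chars[i]
    if (a != "F" && !(relaxed && (a == "Y" || a == "W"))) next
    d <- chars[i + 3L]
    if (d != "D" && d != "E") next
    b <- chars[i + 7L]
    if (b != "R" && b != "K") next
    if (chars[i + 1L] == "X" || chars[i + 2L] == "X" ||
        chars[i + 4L] == "X" || chars[i + 5L] == "X" ||
        chars[i + 6L] == "X") next
    hits <- c(hits, i)
  }
  hits
}

# Exhaustive enumeration of every global alignment path (match, gap in
# a, gap in b) under the affine scheme: a gap run of length L costs
# gap_open + L * gap_extend. Returns the optimal score.
oracle_align_score <- function(a, b, submat, gap_open = -10,
                               gap_extend = -1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, state, score) {
    if (i > na && j > nb) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) {
      rec(i + 1L, j + 1L, 0L, score + submat[ca[i], cb[j]])
    }
    if (i <= na) {
      rec(i + 1L, j, 1L,
          score + gap_extend + if (state != 1L) gap_open else 0)
    }
    if (j <= nb) {
      rec(i, j + 1L, 2L,
          score + gap_extend + if (state != 2L) gap_open else 0)
    }
  }
  rec(1L, 1L, 0L, 0)
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# random unrooted binary tree plus its (additive) path-distance matrix
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(n) runif(n, 0.1, 1))
  list(tree = tr, dm = stats::cophenetic(tr))
}

# brute-force all-offsets template matcher used against classify_s4
oracle_template_offsets <- function(s4_seq, tpl) {
  chars <- strsplit(s4_seq, "", fixed = TRUE)[[1L]]
  w <- length(tpl$slots)
  if (w > length(chars)) return(integer(0))
  ok <- integer(0)
  for (off in seq_len(length(chars) - w + 1L)) {
    match <- TRUE
    for (j in seq_len(w)) {
      ch <- chars[off + j - 1L]
      admits <- switch(tpl$slots[j],
                       basic = c("R", "K"), R = "R", RH = c("R", "H"),
                       I = "I", x = AA20_TEST)
      if (!(ch %in% admits)) { match <- FALSE; break }
    }
    if (match) ok <- c(ok, off)
  }
  ok
}

# scaffold built around the (single) VSD candidate of a planted protein
scaffold_from_planted <- function(record, name = "scaffoldSynth") {
  cand <- assemble_vsd(record, tm_helices(record$sequence),
                       scan_motif(record$sequence, "strict"))
  stopifnot(nrow(cand) >= 1L)
  L <- nchar(record$sequence)
  list(
    scaffold = scaffold_sensor(
      name, record$sequence,
      nterm_span = c(1L, cand$vsd_start[1L] - 1L),
      vsd_span = c(cand$vsd_start[1L], cand$vsd_end[1L]),
      linker_fp_span = c(cand$vsd_end[1L] + 1L, L)),
    candidate = cand[1L, ])
}
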