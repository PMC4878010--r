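# the 20 canonical residues (package alphabet without masked X)
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# weighted residue sampler
draw_residues <- function(n, residues, weights) {
  if (n <= 0L) return(character(0))
  sample(residues, n, replace = TRUE, prob = weights)
}

# Compositions chosen so that windowed hydropathy separates helix from
# background with margin: background stays well below the calling
# threshold, helices well above it even at their edges and around the
# planted charged residues.
.bg_residues <- c("G", "S", "T", "N")
.bg_weights <- c(0.40, 0.30, 0.28, 0.02)
.helix_residues <- c("L", "I", "V", "F")
.helix_weights <- c(0.30, 0.30, 0.30, 0.10)
.s4x_residues <- c("I", "V")
.s4x_weights <- c(0.5, 0.5)

# Build one helix string of length len with `plant` (named character
# vector, names = 1-based offsets within the helix) written over a
# random hydrophobic backdrop.
build_helix <- function(len, residues, weights, plant = character(0)) {
  h <- draw_residues(len, residues, weights)
  if (length(plant) > 0L) h[as.integer(names(plant))] <- plant
  paste(h, collapse = "")
}

# Planted S2 motif: anchor, acidic at +3, basic at +7; the wildcard
# positions are hydrophobic so the helix stays above threshold.
plant_motif <- function(anchor = "F") {
  acidic <- sample(c("D", "E"), 1L)
  basic <- sample(c("R", "K"), 1L)
  xs <- draw_residues(5L, c("L", "I", "V"), rep(1 / 3, 3L))
  plant <- c(anchor, xs[1:2], acidic, xs[3:5], basic)
  names(plant) <- as.character(seq_len(8L))
  plant
}

# Planted S4 template residues for a family, as offset -> residue.
plant_template <- function(family) {
  if (family == "Hv") {
    slots <- c("R", "x", "x", "R", "x", "x", "R")
  } else if (family == "VSP") {
    slots <- c("R", "x", "x", "R", "x", "x", "I", "x", "x", "R", "x",
               "x", sample(c("R", "H"), 1L, prob = c(0.8, 0.2)))
  } else {
    return(character(0))
  }
  res <- ifelse(slots == "x",
                draw_residues(length(slots), .s4x_residues, .s4x_weights),
                slots)
  names(res) <- as.character(seq_along(slots))
  res
}

#' Generate a synthetic proteome with planted VSD architectures
#'
#' Each protein is a hydrophilic background (G/S/T/N-rich) carrying
#' four planted hydrophobic helices (L/I/V/F-rich). Helix 2 contains a
#' planted S2 anchor motif (`Fxx[E,D]xxx[R,K]`); helix 4 contains an S4
#' segment built from the requested family template (`R-x-x-R-x-x-R`
#' for Hv, `R-x-x-R-x-x-I-x-x-R-x-x-(R/H)` for VSP). With
#' `family = "none"` no motif and no template are planted. Point
#' substitutions are applied at `mutation_rate` per residue; at rate 0
#' the planted architecture is untouched, at higher rates mutations may
#' hit any position, including the constrained motif and template
#' slots, by design. Mutation sets are nested across rates at a fixed
#' seed, so recovery degrades monotonically as the rate grows.
#'
#' Identical arguments produce byte-identical output; the caller's RNG
#' state is left untouched.
#'
#' @param n_proteins Number of proteins.
#' @param family `"Hv"`, `"VSP"` or `"none"`; scalar or a vector of
#'   length `n_proteins`.
#' @param seed Integer seed.
#' @param mutation_rate Substitutions per residue in `[0, 1)`.
#' @param anchor Planted motif anchor residue, `"F"` (strict) or
#'   `"Y"`/`"W"` (relaxed-only fixtures).
#' @param background_len,loop_len Length-2 ranges (residues) for the
#'   terminal background segments and inter-helix loops.
#' @param helix_len Length of helices S1, S3 and S4 (default 25).
#' @param s2_len Length of helix S2 (default 27; must fit the motif
#'   with margin).
#' @return A list with `records` (a [protein_records] data frame) and
#'   `truth` (a data frame of planted spans: `s1_start` ... `s4_end`,
#'   `motif_anchor`, `s4_core_start`, `s4_core_end`, `family`).
#' @examples
#' px <- generate_planted_proteome(3, family = "Hv", seed = 1)
#' px$truth
#' @export
generate_planted_proteome <- function(n_proteins, family = "Hv",
                                      seed = 1L, mutation_rate = 0,
                                      anchor = "F",
                                      background_len = c(20L, 40L),
                                      loop_len = c(12L, 30L),
                                      helix_len = 25L, s2_len = 27L) {
  stopifnot(n_proteins >= 1L, mutation_rate >= 0, mutation_rate < 1,
            anchor %in% c("F", "Y", "W"), helix_len >= 15L,
            s2_len >= 21L)
  family <- rep_len(family, n_proteins)
  stopifnot(all(family %in% c("Hv", "VSP", "none")))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  ids <- sprintf("synth%04d", seq_len(n_proteins))
  seqs <- character(n_proteins)
  truth <- vector("list", n_proteins)
  for (p in seq_len(n_proteins)) {
    fam <- family[p]
    nterm <- sample(background_len[1L]:background_len[2L], 1L)
    cterm <- sample(background_len[1L]:background_len[2L], 1L)
    loops <- sample(loop_len[1L]:loop_len[2L], 3L, replace = TRUE)

    motif_off <- (s2_len - 8L) %/% 2L + 1L
    motif <- if (fam == "none") character(0) else {
      m <- plant_motif(anchor)
      names(m) <- as.character(motif_off + as.integer(names(m)) - 1L)
      m
    }
    tpl <- plant_template(fam)
    tpl_off <- if (length(tpl) > 0L) {
      (helix_len - length(tpl)) %/% 2L + 1L
    } else {
      NA_integer_
    }
    if (length(tpl) > 0L) {
      names(tpl) <- as.character(tpl_off + as.integer(names(tpl)) - 1L)
    }

    h1 <- build_helix(helix_len, .helix_residues, .helix_weights)
    h2 <- build_helix(s2_len, .helix_residues, .helix_weights, motif)
    h3 <- build_helix(helix_len, .helix_residues, .helix_weights)
    h4 <- build_helix(helix_len, .s4x_residues, .s4x_weights, tpl)
    bg <- function(n) paste(draw_residues(n, .bg_residues, .bg_weights),
                            collapse = "")
    parts <- c(bg(nterm), h1, bg(loops[1L]), h2, bg(loops[2L]), h3,
               bg(loops[3L]), h4, bg(cterm))
    seq <- paste(parts, collapse = "")

    s1_start <- nterm + 1L
    s1_end <- s1_start + helix_len - 1L
    s2_start <- s1_end + loops[1L] + 1L
    s2_end <- s2_start + s2_len - 1L
    s3_start <- s2_end + loops[2L] + 1L
    s3_end <- s3_start + helix_len - 1L
    s4_start <- s3_end + loops[3L] + 1L
    s4_end <- s4_start + helix_len - 1L

    # nested mutation design: per-position uniforms and replacement
    # draws are consumed for every residue regardless of rate
    L <- nchar(seq)
    u <- stats::runif(L)
    ridx <- sample.int(length(AA20) - 1L, L, replace = TRUE)
    if (mutation_rate > 0) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      hit <- which(u < mutation_rate)
      for (i in hit) {
        chars[i] <- setdiff(AA20, chars[i])[ridx[i]]
      }
      seq <- paste(chars, collapse = "")
    }

    seqs[p] <- seq
    truth[[p]] <- data.frame(
      id = ids[p], family = fam,
      s1_start = s1_start, s1_end = s1_end,
      s2_start = s2_start, s2_end = s2_end,
      s3_start = s3_start, s3_end = s3_end,
      s4_start = s4_start, s4_end = s4_end,
      motif_anchor = if (fam == "none") NA_integer_ else
        s2_start + motif_off - 1L,
      s4_core_start = if (fam == "none") NA_integer_ else
        s4_start + tpl_off - 1L,
      s4_core_end = if (fam == "none") NA_integer_ else
        s4_start + tpl_off + length(tpl) - 2L,
      stringsAsFactors = FALSE)
  }
  list(records = protein_records(ids, seqs),
       truth = do.call(rbind, truth))
}
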