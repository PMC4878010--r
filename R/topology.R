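#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values from the standard Kyte-Doolittle scale;
#' `X` (unknown) is assigned a neutral 0 so that masked residues neither
#' promote nor suppress helix calls.
#'
#' @format Named numeric vector over [AA_ALPHABET_X].
#' @export
KD_SCALE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
              X =  0.0)

#' Windowed Kyte-Doolittle hydropathy profile
#'
#' Computes the arithmetic mean of per-residue hydropathy values in a
#' sliding window of odd width `window`. Scores are defined only where
#' the full window fits, i.e. for centre positions
#' `ceiling(window/2) ... L - floor(window/2)` of a length-`L` sequence.
#'
#' @param seq Amino-acid string over the package alphabet.
#' @param window Odd window width in residues, `3 <= window <=
#'   nchar(seq)`. 19 is the conventional width for transmembrane-helix
#'   detection on this scale.
#' @return An object of class `hydropathy_profile`: a list with
#'   `scores` (numeric, named by 1-based centre position), `window` and
#'   `length` (sequence length).
#' @examples
#' hydropathy_profile(strrep("L", 19), 19)  # single score, 3.8
#' @export
hydropathy_profile <- function(seq, window = 19L) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  validate_sequence(seq)
  window <- as.integer(window)
  L <- nchar(seq)
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  if (window < 3L) stop("window must be >= 3, got ", window)
  if (window > L) {
    stop("window (", window, ") exceeds sequence length (", L, ")")
  }
  vals <- unname(KD_SCALE[strsplit(seq, "", fixed = TRUE)[[1L]]])
  half <- window %/% 2L
  # running mean via filter(); positions where the window fits fully
  means <- as.numeric(stats::filter(vals, rep(1 / window, window),
                                    sides = 2L))
  centres <- (half + 1L):(L - half)
  scores <- means[centres]
  names(scores) <- centres
  structure(list(scores = scores, window = window, length = L),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat("Hydropathy profile: length", x$length, "window", x$window,
      "scores", length(x$scores), "\n")
  invisible(x)
}

#' Predict transmembrane helices from a hydropathy profile
#'
#' Calls maximal runs of window-centre positions whose mean hydropathy
#' is at or above `threshold`. Runs separated by fewer than `min_gap`
#' residues are merged first; merged runs shorter than `min_helix_len`
#' are then discarded. Helices are reported N- to C-terminal and never
#' overlap.
#'
#' The defaults (window 19, threshold 1.6, minimum length 15, gap 3)
#' are the standard operating point of the Kyte-Doolittle scale for
#' membrane-spanning segments.
#'
#' @param profile A [hydropathy_profile()] object.
#' @param threshold Minimum windowed mean hydropathy (dimensionless).
#' @param min_helix_len Minimum helix length in residues.
#' @param min_gap Runs separated by fewer than this many residues are
#'   merged into one helix.
#' @return A data frame with columns `start`, `end` (1-based inclusive)
#'   and `mean_hydropathy` (mean of the defined scores inside the span).
#' @export
predict_tm_helices <- function(profile, threshold = 1.6,
                               min_helix_len = 15L, min_gap = 3L) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0))
  positions <- as.integer(names(profile$scores))
  # small tolerance so scores exactly at threshold are not split by
  # floating-point summation order
  above <- profile$scores >= threshold - 1e-9
  if (!any(above)) return(empty)
  r <- rle(above)
  run_end_idx <- cumsum(r$lengths)
  run_start_idx <- run_end_idx - r$lengths + 1L
  keep <- r$values
  starts <- positions[run_start_idx[keep]]
  ends <- positions[run_end_idx[keep]]
  # merge runs whose separating gap is < min_gap residues
  m_starts <- starts[1L]
  m_ends <- ends[1L]
  for (k in seq_along(starts)[-1L]) {
    gap <- starts[k] - m_ends[length(m_ends)] - 1L
    if (gap < min_gap) {
      m_ends[length(m_ends)] <- ends[k]
    } else {
      m_starts <- c(m_starts, starts[k])
      m_ends <- c(m_ends, ends[k])
    }
  }
  len <- m_ends - m_starts + 1L
  ok <- len >= min_helix_len
  if (!any(ok)) return(empty)
  m_starts <- m_starts[ok]
  m_ends <- m_ends[ok]
  mean_h <- vapply(seq_along(m_starts), function(k) {
    in_span <- positions >= m_starts[k] & positions <= m_ends[k]
    mean(profile$scores[in_span])
  }, numeric(1))
  data.frame(start = m_starts, end = m_ends, mean_hydropathy = mean_h)
}

#' Predict transmembrane helices directly from a sequence
#'
#' Convenience wrapper chaining [hydropathy_profile()] and
#' [predict_tm_helices()].
#'
#' @inheritParams hydropathy_profile
#' @inheritParams predict_tm_helices
#' @return See [predict_tm_helices()]. A sequence shorter than the
#'   window yields no helices.
#' @export
tm_helices <- function(seq, window = 19L, threshold = 1.6,
                       min_helix_len = 15L, min_gap = 3L) {
  if (nchar(seq) < window) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0)))
  }
  predict_tm_helices(hydropathy_profile(seq, window), threshold,
                     min_helix_len, min_gap)
}
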