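#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with an affine gap scheme: a gap
#' run of length L costs `gap_open + L * gap_extend` (both arguments
#' are scores, i.e. negative). Substitution scores come from a named
#' matrix shipped with Biostrings (BLOSUM/PAM families).
#'
#' @param a,b Non-empty amino-acid strings.
#' @param substitution Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open Score for opening a gap run (default -10).
#' @param gap_extend Score per gapped position (default -1).
#' @return A list with `aligned_a`, `aligned_b` (equal-length strings
#'   with `-` for gaps; removing gaps recovers the inputs) and `score`.
#' @examples
#' global_align("RK", "RK")$score  # 10: BLOSUM62 R/R + K/K
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = -10, gap_extend = -1) {
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("cannot align an empty sequence")
  }
  if (gap_open > 0 || gap_extend > 0) {
    stop("gap_open and gap_extend are scores and must be <= 0")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution,
    gapOpening = -gap_open, gapExtension = -gap_extend)
  list(
    aligned_a = as.character(Biostrings::alignedPattern(pa)[[1L]]),
    aligned_b = as.character(Biostrings::alignedSubject(pa)[[1L]]),
    score = Biostrings::score(pa)
  )
}

#' Pairwise p-distance matrix over a record collection
#'
#' For each pair, sequences are globally aligned and the p-distance is
#' the fraction of mismatched columns among aligned columns with no gap
#' in either sequence. A pair whose optimal alignment has zero ungapped
#' columns gets distance 1 with a warning.
#'
#' @param records A [protein_records] data frame with at least two
#'   rows.
#' @inheritParams global_align
#' @return A symmetric numeric matrix with zero diagonal, dimnames set
#'   to the record ids, entries in `[0, 1]`.
#' @export
pairwise_distances <- function(records, substitution = "BLOSUM62",
                               gap_open = -10, gap_extend = -1) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records")
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align(records$sequence[i], records$sequence[j],
                         substitution, gap_open, gap_extend)
      ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1L]]
      cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1L]]
      ungapped <- ca != "-" & cb != "-"
      if (!any(ungapped)) {
        warning("alignment of '", records$id[i], "' and '",
                records$id[j], "' has no ungapped columns; distance 1")
        p <- 1
      } else {
        p <- sum(ca[ungapped] != cb[ungapped]) / sum(ungapped)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration. At each step the pair
#' minimising the Q-criterion is joined; ties are broken by the lowest
#' (row, column) index pair in current label order, so the output is
#' deterministic given input order. Negative intermediate branch
#' lengths are clamped to zero with the deficit shifted to the sister
#' branch (total preserved). The result is an unrooted tree; on an
#' additive matrix the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and dimnames
#'   (labels); at least 3 labels.
#' @return An [ape::phylo] object (unrooted, basal trifurcation).
#' @examples
#' d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(d)$edge.length  # 1, 3, 5
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n0 <- nrow(dm)
  if (n0 < 3L) stop("neighbor joining needs at least 3 labels")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n0))
  stopifnot(isSymmetric(unname(dm)), all(diag(dm) == 0))

  # node ids: 1..n0 tips, internal nodes numbered onwards
  ids <- seq_len(n0)
  next_id <- n0 + 1L
  edges <- matrix(integer(0), 0L, 2L)
  lens <- numeric(0)
  D <- dm

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    c(li, lj)
  }

  while (length(ids) > 3L) {
    n <- length(ids)
    r <- unname(rowSums(D))
    Q <- (n - 2) * D - outer(r, r, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    l <- clamp_pair(li, lj)
    edges <- rbind(edges, c(next_id, ids[i]), c(next_id, ids[j]))
    lens <- c(lens, l[1L], l[2L])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- D[-j, -j, drop = FALSE]
    dnew <- dnew[-j]
    D[i, ] <- dnew
    D[, i] <- dnew
    D[i, i] <- 0
    ids[i] <- next_id
    ids <- ids[-j]
    next_id <- next_id + 1L
  }
  # final trifurcation via the three-point formulas
  D <- unname(D)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- D[1, 2] - la
  lc <- D[1, 3] - la
  ab <- clamp_pair(la, lb); la <- ab[1L]; lb <- ab[2L]
  lc <- max(0, lc)
  edges <- rbind(edges, c(next_id, ids[1L]), c(next_id, ids[2L]),
                 c(next_id, ids[3L]))
  lens <- c(lens, la, lb, lc)
  root_id <- next_id

  # renumber to ape convention: tips 1..n0, root n0+1, internals above
  internal <- unique(edges[edges > n0])
  internal <- c(root_id, setdiff(internal, root_id))
  map <- integer(max(internal))
  map[internal] <- n0 + seq_along(internal)
  renum <- function(v) ifelse(v > n0, map[v], v)
  edge <- cbind(renum(edges[, 1L]), renum(edges[, 2L]))
  tree <- structure(list(edge = edge, edge.length = lens,
                         tip.label = labels,
                         Nnode = length(internal)),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

# quote a Newick label if it contains characters with syntactic meaning
quote_newick_label <- function(x) {
  needs <- grepl("[][(),:;'\" \t]", x)
  ifelse(needs, paste0("'", gsub("'", "''", x), "'"), x)
}

#' Serialize a tree to Newick
#'
#' Writes branch lengths at full double precision and single-quotes
#' labels containing Newick-reserved characters, so re-parsing
#' reproduces topology and lengths.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return The output path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(node, len) {
    sub <- if (node <= n_tip) {
      quote_newick_label(tree$tip.label[node])
    } else {
      kid_edges <- children[[as.character(node)]]
      paste0("(", paste(vapply(kid_edges, function(e) {
        fmt(tree$edge[e, 2L], tree$edge.length[e])
      }, character(1)), collapse = ","), ")")
    }
    if (is.na(len)) sub else sprintf("%s:%.17g", sub, len)
  }
  root <- n_tip + 1L
  writeLines(paste0(fmt(root, NA_real_), ";"), path)
  invisible(path)
}

#' Build a neighbor-joining tree from protein records
#'
#' Convenience wrapper: [pairwise_distances()] then
#' [neighbor_joining()].
#'
#' @inheritParams pairwise_distances
#' @return An [ape::phylo] object.
#' @export
nj_tree <- function(records, substitution = "BLOSUM62",
                    gap_open = -10, gap_extend = -1) {
  neighbor_joining(pairwise_distances(records, substitution,
                                      gap_open, gap_extend))
}
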