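test_that("alignment scores follow the substitution matrix on gap-free pairs", {
  al <- global_align("RK", "RK")
  expect_identical(al$score, 10)          # BLOSUM62 R/R + K/K
  expect_identical(al$aligned_a, "RK")

  withr::local_seed(51)
  for (k in seq_len(20)) {
    s <- random_seq(sample(3:25, 1))
    self <- global_align(s, s)
    chars <- strsplit(s, "")[[1L]]
    expect_equal(self$score, sum(blosum62[cbind(chars, chars)]),
                 ignore_attr = TRUE)
    expect_identical(self$aligned_a, s)
    expect_identical(self$aligned_b, s)
  }
  expect_error(global_align("", "RK"), "empty")
})

test_that("alignment is symmetric and gaps strip back to the inputs", {
  withr::local_seed(52)
  for (k in seq_len(30)) {
    a <- random_seq(sample(2:20, 1))
    b <- random_seq(sample(2:20, 1))
    al <- global_align(a, b)
    expect_identical(al$score, global_align(b, a)$score)
    expect_identical(nchar(al$aligned_a), nchar(al$aligned_b))
    expect_identical(gsub("-", "", al$aligned_a), a)
    expect_identical(gsub("-", "", al$aligned_b), b)
  }
})

test_that("alignment score equals exhaustive path enumeration on short pairs", {
  withr::local_seed(53)
  for (k in seq_len(40)) {
    a <- random_seq(sample(1:6, 1))
    b <- random_seq(sample(1:6, 1))
    expect_identical(global_align(a, b)$score,
                     oracle_align_score(a, b, blosum62))
  }
})

test_that("p-distances: identity, hand case, and matrix invariants", {
  recs <- protein_records(c("a", "b"), c("AAAA", "AAAA"))
  expect_identical(pairwise_distances(recs)["a", "b"], 0)

  # positive diagonal forces the gap-free alignment: 1 mismatch / 4
  recs2 <- protein_records(c("a", "b"), c("AAAA", "AAAT"))
  expect_identical(pairwise_distances(recs2)["a", "b"], 0.25)

  withr::local_seed(54)
  recs3 <- random_records(5, len_range = c(10L, 30L))
  d <- pairwise_distances(recs3)
  expect_identical(d, t(d))
  expect_identical(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("three-taxon neighbor joining reproduces the closed form", {
  d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  lens <- tr$edge.length[match(1:3, tr$edge[, 2L])]
  expect_equal(lens, c(1, 3, 5))
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive trees exactly", {
  withr::local_seed(55)
  for (k in seq_len(15)) {
    case <- random_additive_case(sample(5:10, 1))
    tr <- neighbor_joining(case$dm)
    expect_identical(as.integer(ape::dist.topo(tr, case$tree)), 0L)
    back <- stats::cophenetic(tr)[rownames(case$dm), colnames(case$dm)]
    expect_lt(max(abs(back - case$dm)), 1e-9)
  }
})

test_that("an equidistant matrix resolves with equal terminal branches", {
  n <- 6L
  d <- matrix(2, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(d) <- 0
  tr <- neighbor_joining(d)
  term <- tr$edge.length[tr$edge[, 2L] <= n]
  expect_equal(term, rep(1, n))
  internal <- tr$edge.length[tr$edge[, 2L] > n]
  expect_equal(internal, rep(0, length(internal)))
})

test_that("NJ against an independent implementation on noisy matrices", {
  withr::local_seed(56)
  for (k in seq_len(10)) {
    n <- sample(5:9, 1)
    case <- random_additive_case(n)
    dm <- case$dm + matrix(runif(n * n, 0, 0.02), n, n)
    dm <- (dm + t(dm)) / 2
    diag(dm) <- 0
    mine <- neighbor_joining(dm)
    ref <- ape::nj(as.dist(dm))
    expect_identical(as.integer(ape::dist.topo(mine, ref)), 0L)
  }
})

test_that("newick serialization round-trips topology and branch lengths", {
  d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(sort(back$edge.length), sort(tr$edge.length))

  withr::local_seed(57)
  case <- random_additive_case(8)
  tr8 <- neighbor_joining(case$dm)
  f8 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr8, f8)
  back8 <- ape::read.tree(f8)
  expect_identical(as.integer(ape::dist.topo(back8, tr8)), 0L)
  expect_lt(max(abs(sort(back8$edge.length) - sort(tr8$edge.length))),
            1e-12)
})

test_that("labels needing quotes are quoted per Newick rules", {
  d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3)
  labs <- c("sp. 1", "pl(ain", "ok")
  dimnames(d) <- list(labs, labs)
  tr <- neighbor_joining(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  txt <- readLines(f)
  expect_match(txt, "'sp. 1'", fixed = TRUE)
  expect_match(txt, "'pl(ain'", fixed = TRUE)
  expect_match(txt, "ok:")  # unreserved label stays bare
})
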