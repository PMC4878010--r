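test_that("windowed means reproduce hand-computed scale values", {
  # 19 L residues, window 19: single defined score, the L scale value
  p <- hydropathy_profile(strrep("L", 19), 19)
  expect_length(p$scores, 1L)
  expect_identical(names(p$scores), "10")
  expect_equal(unname(p$scores), 3.8)

  # constant sequence: every score equals the residue's scale value
  g <- hydropathy_profile(strrep("G", 60), 19)
  expect_equal(unname(g$scores), rep(-0.4, 60 - 18), tolerance = 1e-12)
  expect_identical(names(g$scores)[1L], "10")
  expect_identical(names(g$scores)[length(g$scores)], "51")

  # X scores 0: all-X profile is flat zero
  x <- hydropathy_profile(strrep("X", 21), 3)
  expect_equal(unname(x$scores), rep(0, 19))
})

test_that("window preconditions are enforced", {
  expect_error(hydropathy_profile("GGGGG", 7), "exceeds sequence length")
  expect_error(hydropathy_profile("GGGGGGGG", 4), "odd")
  expect_error(hydropathy_profile(strrep("G", 10), 1), ">= 3")
})

test_that("a planted hydrophobic stretch is called as one helix", {
  seq <- paste0(strrep("G", 40), strrep("L", 25), strrep("G", 40))
  h <- tm_helices(seq)
  expect_identical(nrow(h), 1L)
  planted <- 41:65
  called <- h$start[1L]:h$end[1L]
  expect_gte(length(intersect(called, planted)) / length(planted), 0.9)
  expect_gt(h$mean_hydropathy[1L], 1.6)
})

test_that("all-background sequences yield no helices", {
  expect_identical(nrow(tm_helices(strrep("G", 80))), 0L)
  expect_identical(nrow(tm_helices("GGG")), 0L)  # shorter than window
})

test_that("stretches separated by 2 residues come out as one helix", {
  seq <- paste0(strrep("G", 30), strrep("L", 20), "GG", strrep("L", 20),
                strrep("G", 30))
  merged <- tm_helices(seq, min_gap = 3L)
  expect_identical(nrow(merged), 1L)

  seq2 <- paste0(strrep("G", 30), strrep("L", 20), strrep("G", 30),
                 strrep("L", 20), strrep("G", 30))
  split <- tm_helices(seq2, min_gap = 3L)
  expect_identical(nrow(split), 2L)
  expect_lt(split$end[1L], split$start[2L])
})

test_that("run merging and short-run discard follow min_gap/min_helix_len", {
  # hand-built profile: above-threshold runs at 10-30 and 33-60 with a
  # 2-position dip between them, plus an isolated 4-position run
  scores <- c(rep(1, 21), rep(0, 2), rep(1, 28), rep(0, 10), rep(1, 4))
  names(scores) <- seq(10, length.out = length(scores))
  prof <- structure(list(scores = scores, window = 19L,
                         length = max(as.integer(names(scores))) + 9L),
                    class = "hydropathy_profile")
  merged <- predict_tm_helices(prof, threshold = 0.5,
                               min_helix_len = 5L, min_gap = 3L)
  expect_identical(merged$start, c(10L))
  expect_identical(merged$end, c(60L))

  unmerged <- predict_tm_helices(prof, threshold = 0.5,
                                 min_helix_len = 5L, min_gap = 2L)
  expect_identical(unmerged$start, c(10L, 33L))
  expect_identical(unmerged$end, c(30L, 60L))
  # the trailing 4-long run is below min_helix_len in both cases
  expect_identical(nrow(merged), 1L)
  expect_identical(nrow(unmerged), 2L)
})

test_that("raising the threshold shrinks the above-threshold set", {
  withr::local_seed(7)
  for (k in seq_len(20)) {
    seq <- paste(sample(c("G", "L", "I", "S", "V", "N"), 120,
                        replace = TRUE), collapse = "")
    p <- hydropathy_profile(seq, 19)
    n_above <- vapply(c(0.5, 1.0, 1.6, 2.2),
                      function(th) sum(p$scores >= th), numeric(1))
    expect_true(all(diff(n_above) <= 0))
  }
})

test_that("predictions mirror under sequence reversal", {
  withr::local_seed(8)
  for (k in seq_len(20)) {
    seq <- paste(sample(c("G", "S", "L", "I", "V"), 150, replace = TRUE),
                 collapse = "")
    fwd <- tm_helices(seq)
    rev_seq <- paste(rev(strsplit(seq, "")[[1L]]), collapse = "")
    bwd <- tm_helices(rev_seq)
    L <- nchar(seq)
    mirrored <- data.frame(start = rev(L - bwd$end + 1L),
                           end = rev(L - bwd$start + 1L))
    expect_identical(fwd$start, mirrored$start)
    expect_identical(fwd$end, mirrored$end)
  }
})
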