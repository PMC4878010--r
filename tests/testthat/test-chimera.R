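test_that("scaffold spans must partition the sequence", {
  expect_s3_class(scaffold_sensor("s", strrep("A", 30), c(1, 10),
                                  c(11, 20), c(21, 30)),
                  "scaffold_sensor")
  expect_error(scaffold_sensor("s", strrep("A", 30), c(1, 10),
                               c(12, 20), c(21, 30)), "partition")
  expect_error(scaffold_sensor("s", strrep("A", 30), c(1, 10),
                               c(11, 20), c(21, 29)), "partition")
  expect_error(scaffold_sensor("s", strrep("A", 30), c(10, 1),
                               c(11, 20), c(21, 30)), "malformed")
})

test_that("an identity swap reproduces the scaffold sequence", {
  px <- generate_planted_proteome(1, family = "Hv", seed = 61)
  rec <- px$records[1L, ]
  sc <- scaffold_from_planted(rec)
  design <- build_chimera(sc$scaffold, sc$candidate, rec)
  expect_identical(design$sequence, sc$scaffold$sequence)
})

test_that("product length and part map follow the swap arithmetic", {
  px <- generate_planted_proteome(2, family = c("Hv", "VSP"), seed = 62)
  rec_s <- px$records[1L, ]
  rec_d <- px$records[2L, ]
  sc <- scaffold_from_planted(rec_s)
  cand_d <- assemble_vsd(rec_d, tm_helices(rec_d$sequence),
                         scan_motif(rec_d$sequence, "strict"))[1L, ]
  design <- build_chimera(sc$scaffold, cand_d, rec_d)

  sc_vsd_len <- diff(sc$scaffold$vsd_span) + 1L
  donor_len <- cand_d$vsd_end - cand_d$vsd_start + 1L
  expect_identical(nchar(design$sequence),
                   nchar(sc$scaffold$sequence) - sc_vsd_len + donor_len)

  # part map partitions the product with no gaps or overlaps
  pm <- design$part_map
  expect_identical(pm$start, c(1L, pm$end[1L] + 1L, pm$end[2L] + 1L))
  expect_identical(pm$end[3L], nchar(design$sequence))

  # donor VSD appears verbatim, flanked by the exact scaffold pieces
  donor_vsd <- substring(rec_d$sequence, cand_d$vsd_start,
                         cand_d$vsd_end)
  expect_identical(substring(design$sequence, pm$start[2L], pm$end[2L]),
                   donor_vsd)
  expect_identical(
    substring(design$sequence, 1L, pm$end[1L]),
    substring(sc$scaffold$sequence, 1L, sc$scaffold$nterm_span[2L]))
  expect_identical(
    substring(design$sequence, pm$start[3L], pm$end[3L]),
    substring(sc$scaffold$sequence, sc$scaffold$linker_fp_span[1L],
              sc$scaffold$linker_fp_span[2L]))
})

test_that("swapping in and back out restores the scaffold byte-for-byte", {
  px <- generate_planted_proteome(6, family = "VSP", seed = 63)
  rec_s <- px$records[1L, ]
  sc <- scaffold_from_planted(rec_s)
  for (k in 2:6) {
    rec_d <- px$records[k, ]
    cand_d <- assemble_vsd(rec_d, tm_helices(rec_d$sequence),
                           scan_motif(rec_d$sequence, "strict"))[1L, ]
    fwd <- build_chimera(sc$scaffold, cand_d, rec_d)
    pm <- fwd$part_map
    # treat the product as a scaffold and swap the original VSD back
    sc2 <- scaffold_sensor("product", fwd$sequence,
                           c(1L, pm$end[1L]),
                           c(pm$start[2L], pm$end[2L]),
                           c(pm$start[3L], pm$end[3L]))
    orig <- list(record_id = rec_s$id,
                 vsd_start = sc$scaffold$vsd_span[1L],
                 vsd_end = sc$scaffold$vsd_span[2L])
    back <- build_chimera(sc2, orig, rec_s)
    expect_identical(back$sequence, sc$scaffold$sequence)
  }
})

test_that("mismatched ids and out-of-range donor spans are errors", {
  px <- generate_planted_proteome(1, family = "Hv", seed = 64)
  rec <- px$records[1L, ]
  sc <- scaffold_from_planted(rec)
  bad <- sc$candidate
  bad$record_id <- "someone_else"
  expect_error(build_chimera(sc$scaffold, bad, rec), "does not match")
  bad2 <- sc$candidate
  bad2$vsd_end <- nchar(rec$sequence) + 10L
  expect_error(build_chimera(sc$scaffold, bad2, rec), "exceeds")
})

test_that("the cloning note names both restriction sites and the span", {
  px <- generate_planted_proteome(1, family = "Hv", seed = 65)
  rec <- px$records[1L, ]
  sc <- scaffold_from_planted(rec)
  design <- build_chimera(sc$scaffold, sc$candidate, rec)
  note <- flank_for_cloning(design)
  expect_match(note, "BamHI")
  expect_match(note, "EcoRV")
  pm <- design$part_map
  expect_identical(attr(note, "span"),
                   c(pm$start[2L], pm$end[2L]))
  # identity swap: the note carries the scaffold's own VSD span
  expect_identical(attr(note, "span"),
                   c(sc$scaffold$vsd_span[1L], sc$scaffold$vsd_span[2L]))
})
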