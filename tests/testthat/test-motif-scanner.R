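make_planted_msa <- function(n = 10, ncol = 100, colA = 10, colB = c(40, 41),
                             colC = 70, triad = "NDD", seed = 1) {
  make_rdrp_msa(n, ncol, triads = triad, colA = colA, colB = colB,
                colC = colC, seed = seed)
}

test_that("anchors are found at planted columns and support is reported", {
  msa <- make_planted_msa()
  an <- locate_motif_anchors(msa)
  expect_true(an$found)
  expect_equal(an$colA, 10)
  expect_equal(an$colB, c(40, 41))
  expect_equal(an$colC, 70)
  expect_true(all(an$support >= 0.7))
  expect_true(an$colA < an$colB[1] && an$colB[2] < an$colC)
})

test_that("random alignments yield a no-anchor result, ragged MSAs an error", {
  set.seed(5)
  msa <- setNames(replicate(8, random_protein(80)), paste0("s", 1:8))
  an <- locate_motif_anchors(msa)
  expect_false(an$found)
  expect_error(locate_motif_anchors(c(a = "ACD", b = "AC")), "ragged")
  expect_error(locate_motif_anchors(c(a = "ACD")), "at least 2")
})

test_that("anchors are invariant under row reordering", {
  msa <- make_planted_msa(seed = 8)
  an1 <- locate_motif_anchors(msa)
  an2 <- locate_motif_anchors(rev(msa))
  expect_equal(an1[c("colA", "colB", "colC")], an2[c("colA", "colB", "colC")])
})

test_that("generator anchors are recovered across seeds", {
  for (s in 1:20) {
    msa <- make_rdrp_msa(n_seqs = 8, n_col = 110, triads = c("NDD", "GDQ"),
                         colA = 15, colB = c(45, 46), colC = 80, seed = s)
    an <- locate_motif_anchors(msa)
    tr <- attr(msa, "truth")
    expect_true(an$found, info = paste("seed", s))
    expect_equal(an$colC, tr$colC, info = paste("seed", s))
    expect_equal(an$colA, tr$colA, info = paste("seed", s))
    expect_equal(an$colB, tr$colB, info = paste("seed", s))
  }
})

test_that("triads are read at colC +/- 1, tallied, and gaps mark incomplete", {
  msa <- c(s1 = "AAAAGDDAAA", s2 = "AAAANDDAAA", s3 = "AAAANDDAAA",
           s4 = "AAAA-DDAAA")
  tri <- extract_triads(msa, list(colC = 6))
  expect_equal(tri$calls$triad, c("GDD", "NDD", "NDD", "-DD"))
  expect_equal(tri$calls$status,
               c("canonical", "novel", "novel", "incomplete"))
  expect_equal(tri$tally, c(GDD = 1L, NDD = 2L))
  expect_equal(tri$mode, "NDD")
  expect_equal(sum(tri$tally),
               sum(tri$calls$status != "incomplete"))
  expect_error(extract_triads(msa, list(colC = 1)), "edge")
})

test_that("triad classification follows the catalog", {
  expect_equal(classify_triad("GDD"), "canonical")
  expect_equal(classify_triad("SDD"), "known_rare")
  expect_equal(classify_triad("GDN"), "known_rare")
  expect_equal(classify_triad("GDQ"), "novel")
  expect_equal(classify_triad("NDD"), "novel")
  expect_error(classify_triad("GD"), "3-character")
  # catalog fully configurable
  expect_equal(classify_triad("NDD",
                              list(canonical = "NDD", known_rare = "GDD")),
               "canonical")
})

test_that("planted triads are fully recovered under anchor-column noise", {
  for (s in 1:10) {
    msa <- make_rdrp_msa(n_seqs = 12, n_col = 100,
                         triads = c("NDD", "SDD", "HDD", "GDQ"),
                         colA = 12, colB = c(44, 45), colC = 75,
                         noise = 0.25, seed = 100 + s)
    an <- locate_motif_anchors(msa, min_frac = 0.7)
    expect_true(an$found, info = paste("seed", s))
    tri <- extract_triads(msa, an)
    expect_equal(unname(tri$calls$triad),
                 unname(attr(msa, "truth")$triads),
                 info = paste("seed", s))
  }
})

test_that("triad-by-clade cross-tabulation joins calls with assignments", {
  calls <- data.frame(seq_id = c("a", "b", "c", "d"),
                      triad = c("GDQ", "GDQ", "NDD", "-DD"),
                      status = c("novel", "novel", "novel", "incomplete"))
  clades <- data.frame(id = c("a", "b", "c", "d"),
                       clade = c("clade_1", "clade_1", "clade_2", "clade_2"))
  tab <- triads_by_clade(calls, clades)
  expect_equal(unname(tab["GDQ", "clade_1"]), 2L)
  expect_equal(unname(tab["GDQ", "clade_2"]), 0L)   # GDQ exclusive to clade_1
  expect_false("-DD" %in% rownames(tab))
})
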