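test_that("terminal conservation counts positional mismatches only", {
  a <- paste0(strrep("A", 20), random_dna(60), strrep("G", 20))
  b <- a
  td <- terminal_conservation(a, b)
  expect_equal(td$mism5, 0L)
  expect_equal(td$mism3, 0L)

  b2 <- b
  substr(b2, 5, 5) <- "C"              # one 5'-terminal difference
  td2 <- terminal_conservation(a, b2)
  expect_equal(td2$mism5, 1L)
  expect_equal(td2$mism3, 0L)

  expect_error(terminal_conservation("ACGT", a), "at least k")
})

test_that("random termini mismatch at the 0.75k Monte-Carlo rate", {
  set.seed(55)
  k <- 20
  mism <- replicate(1000, {
    terminal_conservation(random_dna(40), random_dna(40), k = k)$mism5
  })
  expect_equal(mean(mism), 0.75 * k, tolerance = 0.02)
})

test_that("Ct binarization applies the cutoff and is monotone", {
  ct <- matrix(c(24.67, 39.0, NA, 38.0), 2, 2,
               dimnames = list(c("v1", "v2"), c("s1", "s2")))
  pres <- binarize_ct(ct)
  expect_true(pres["v1", "s1"])       # Ct 24.67 -> present
  expect_false(pres["v2", "s1"])      # Ct 39 -> absent
  expect_false(pres["v1", "s2"])      # blank -> absent
  expect_true(pres["v2", "s2"])       # boundary: Ct == cutoff is present

  # raising the cutoff never turns a present cell absent
  set.seed(6)
  m <- matrix(runif(40, 15, 45), 5, 8)
  for (cut in c(20, 30, 38, 44)) {
    lo <- binarize_ct(m, cut)
    hi <- binarize_ct(m, cut + 1)
    expect_true(all(hi[lo]))
  }
})

test_that("co-occurrence over the printed yeast panel behaves as reported", {
  ct <- read_ct_table(study_file("study_yeast_ct.tsv"))
  pres <- binarize_ct(ct, cutoff = 38)
  # SbOMV1 RNA1 and RNA2 always found together (Cz12, Cz16, Cz25)
  co <- cooccurrence_score(pres["SbOMV1 RNA1", ], pres["SbOMV1 RNA2", ])
  expect_equal(co$jaccard, 1.0)
  expect_true(co$exact)
  expect_equal(co$n_shared_positive, 3L)
  expect_equal(sort(names(which(pres["SbOMV1 RNA1", ]))),
               c("Cz12", "Cz16", "Cz25"))
  # the mitovirus panel prints Ct 34,43 (Cz1) and 23,08 (Cz12): two
  # positives at the cutoff, one shared with the ormycovirus
  expect_setequal(names(which(pres["SbMV1", ])), c("Cz1", "Cz12"))
  co2 <- cooccurrence_score(pres["SbOMV1 RNA1", ], pres["SbMV1", ])
  expect_equal(co2$jaccard, 1 / 4)
  expect_false(co2$exact)

  expect_warning(
    z <- cooccurrence_score(c(a = FALSE), c(a = FALSE)), "empty")
  expect_equal(z$jaccard, 0)
  expect_error(cooccurrence_score(c(a = TRUE), c(b = TRUE)), "sample sets")
})

test_that("jaccard is symmetric and 1 only for equal non-empty sets", {
  set.seed(77)
  for (i in 1:25) {
    a <- runif(6) < 0.5
    b <- runif(6) < 0.5
    names(a) <- names(b) <- paste0("s", 1:6)
    ab <- suppressWarnings(cooccurrence_score(a, b))
    ba <- suppressWarnings(cooccurrence_score(b, a))
    expect_equal(ab$jaccard, ba$jaccard)
    expect_equal(ab$jaccard == 1, all(a == b) && any(a))
  }
})

test_that("abundance correlation is Pearson on log10(count + 1)", {
  # proportional vectors are near-perfectly correlated on the log scale
  # (the +1 pseudocount perturbs exact affinity)
  a <- c(10, 100, 1000, 50)
  r <- abundance_correlation(a, 2 * a)
  expect_equal(r$r, 1.0, tolerance = 1e-3)
  # exactly affine on the transformed scale: r = 1 to machine precision
  b <- (a + 1)^2 - 1
  expect_equal(abundance_correlation(a, b)$r, 1.0, tolerance = 1e-12)

  # zero-in-both libraries are dropped; constant vectors are undefined
  expect_warning(rc <- abundance_correlation(c(5, 5, 5, 0), c(1, 2, 3, 0)),
                 "constant")
  expect_true(is.na(rc$r))
  expect_equal(rc$n_libraries_used, 3L)
  r2 <- abundance_correlation(c(1, 2, 0, 0), c(3, 4, 0, 0))
  expect_true(is.na(r2$r))             # fewer than 3 libraries remain
})

test_that("the printed PvlaOMV3 segment counts correlate like the oracle", {
  counts <- read_strand_counts(study_file("study_read_counts.tsv"))
  r1 <- counts[counts$segment_id == "PvlaOMV3 RNA1", ]
  r2 <- counts[counts$segment_id == "PvlaOMV3 RNA2", ]
  libs <- c("DMGA", "DMGE", "DMGD", "PMA", "PMGA")
  a <- r1$total[match(libs, r1$library_id)]
  b <- r2$total[match(libs, r2$library_id)]
  expect_equal(a, c(2654, 244, 3338, 840, 3788))
  expect_equal(b, c(3160, 600, 3002, 1060, 2844))
  got <- abundance_correlation(a, b)
  exp <- oracle_pearson(log10(a + 1), log10(b + 1))
  expect_equal(got$r, exp, tolerance = 1e-12)
  expect_equal(got$n_libraries_used, 5L)
})

test_that("association calls combine STRONG/MODERATE/WEAK evidence", {
  rules <- association_rules()
  # conserved termini alone are sufficient (the RACE-confirmed case)
  a1 <- call_association("r1", "r2",
                         terminal = list(k = 20, mism5 = 1L, mism3 = 0L),
                         rules = rules)
  expect_equal(a1$call, "associated")
  expect_true(a1$strong)

  # exact co-occurrence plus strong correlation
  a2 <- call_association("r1", "r2",
                         cooccurrence = list(jaccard = 1, exact = TRUE,
                                             n_shared_positive = 3L),
                         correlation = list(r = 0.95,
                                            n_libraries_used = 5L),
                         rules = rules)
  expect_equal(a2$call, "associated")

  # correlation alone is not enough
  a3 <- call_association("r1", "r2",
                         correlation = list(r = 0.95,
                                            n_libraries_used = 5L),
                         rules = rules)
  expect_equal(a3$call, "unresolved")

  expect_error(call_association("r1", "r2"), "at least one")
})

test_that("all true pairs and no cross pairs associate on clean bundles", {
  for (s in c(2, 9)) {
    out <- tempfile()
    b <- generate_dataset(synthetic_params(seed = s), out)
    seqs <- setNames(b$contigs$seq, b$contigs$id)
    pres <- binarize_ct(read_ct_table(b$paths$ct))
    long <- read_strand_counts(b$paths$counts)
    counts <- tapply(long$total, list(long$segment_id, long$library_id), sum)
    rna1 <- vapply(b$manifest$pairings, `[[`, character(1), "rna1")
    rna2 <- vapply(b$manifest$pairings, `[[`, character(1), "rna2")
    ev <- associate_segments(rna1, rna2, seqs = seqs, presence = pres,
                             counts = counts)
    truth <- paste(rna1, rna2)
    called <- paste(ev$rna1_id, ev$rna2_id)[ev$call == "associated"]
    expect_setequal(called, truth)     # precision = recall = 1
    unlink(out, recursive = TRUE)
  }
})
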