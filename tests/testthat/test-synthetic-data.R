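test_that("planted RdRP contigs satisfy their own annotations", {
  for (s in 1:5) {
    rc <- make_rdrp_contig(1500, "GDQ", seed = s)
    tr <- rc$truth
    expect_gt(tr$mass_da, 15000)
    # the triad sits at the annotated protein position
    expect_equal(substr(tr$protein, tr$motif$posC - 1, tr$motif$posC + 1),
                 "GDQ")
    expect_equal(substr(tr$protein, tr$motif$posA_D, tr$motif$posA_D), "D")
    expect_equal(substr(tr$protein, tr$motif$posB[1], tr$motif$posB[2]), "GG")
    # the annotated ORF is found by the caller with the same protein
    orfs <- find_orfs(rc$contig)
    hit <- orfs[orfs$start == tr$orf_start & orfs$end == tr$orf_end &
                  orfs$strand == "+", ]
    expect_equal(hit$protein[1], tr$protein)
  }
  expect_error(make_rdrp_contig(800, "NDD", seed = 1), "too short")
  expect_error(make_rdrp_contig(1500, "GG", seed = 1), "triad")
  # determinism
  expect_identical(make_rdrp_contig(1400, "NDD", seed = 5),
                   make_rdrp_contig(1400, "NDD", seed = 5))
})

test_that("error-free reads are exact substrings; all-plus decodes all-plus", {
  rc <- make_rdrp_contig(1300, "NDD", seed = 3)
  reads <- simulate_stranded_reads(rc$contig, depth = 50, plus_fraction = 1.0,
                                   seed = 4)
  expect_equal(attr(reads, "n_minus"), 0L)
  tf <- tempfile(); writeLines(c("@HD\tVN:1.6", reads), tf)
  tl <- tally_strand(read_alignments(tf), "fr_firststrand")
  expect_equal(tl$minus, 0L)
  expect_equal(tl$plus, length(reads))
  # every read sequence is a substring of the contig or its revcomp
  seqs <- vapply(strsplit(reads, "\t"), `[[`, character(1), 10)
  ok <- vapply(seqs, function(s)
    grepl(s, rc$contig$seq, fixed = TRUE) ||
      grepl(s, revcomp(rc$contig$seq), fixed = TRUE), logical(1))
  expect_true(all(ok))
})

test_that("bundles are complete, consistent with truth, and deterministic", {
  p <- synthetic_params(seed = 13)
  out1 <- tempfile(); out2 <- tempfile()
  b <- generate_dataset(p, out1)
  b2 <- generate_dataset(p, out2)

  # deterministic: byte-identical files
  for (nm in c("contigs", "hits", "ct", "counts", "msa")) {
    expect_identical(readLines(b$paths[[nm]]), readLines(b2$paths[[nm]]),
                     info = nm)
  }
  expect_identical(readLines(b$paths$sam[[1]]), readLines(b2$paths$sam[[1]]))

  # manifest lists n_viruses RNA1/RNA2 pairs
  expect_length(b$manifest$pairings, p$n_viruses)
  labels <- unlist(b$manifest$labels)
  expect_equal(sum(labels == "viral_rna1"), p$n_viruses)
  expect_equal(sum(labels == "viral_rna2"), p$n_viruses)

  # hits contain every host contig and no viral contig
  hits <- read_hits_table(b$paths$hits)
  expect_setequal(hits, names(labels)[labels == "host"])

  # SAM parses cleanly
  for (sam in b$paths$sam) {
    expect_no_warning(al <- read_alignments(sam))
    expect_true(all(al$is_mapped))
  }

  # Ct presence equals manifest presence at the default cutoff
  pres <- binarize_ct(read_ct_table(b$paths$ct))
  for (v in names(b$manifest$presence)) {
    truth_samples <- unlist(b$manifest$presence[[v]])
    for (seg in paste0(v, c("_RNA1", "_RNA2"))) {
      expect_setequal(colnames(pres)[pres[seg, ]], truth_samples)
    }
  }

  # RNA1/RNA2 pairs share identical k-nt termini
  seqs <- setNames(b$contigs$seq, b$contigs$id)
  for (pr in b$manifest$pairings) {
    td <- terminal_conservation(seqs[[pr$rna1]], seqs[[pr$rna2]],
                                k = p$terminal_k)
    expect_equal(td$mism5 + td$mism3, 0L)
  }
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("inconsistent parameters are rejected", {
  expect_error(generate_dataset(synthetic_params(n_samples = 0L, seed = 1),
                                tempfile()), "n_samples")
  expect_error(generate_dataset(synthetic_params(n_viruses = 40L,
                                                 n_samples = 2L, seed = 1),
                                tempfile()), "distinct presence")
})
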