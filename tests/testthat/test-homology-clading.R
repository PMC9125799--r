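test_that("global alignment handles identity and forced gaps", {
  al <- global_align("ACD", "ACD")
  expect_equal(nchar(al$aligned_a), 3L)
  expect_equal(al$identity_pct, 100)

  al2 <- global_align("ACD", "AD", gap_open = 50)
  expect_equal(nchar(al2$aligned_a), 3L)
  expect_equal(sum(strsplit(al2$aligned_b, "")[[1]] == "-"), 1L)
})

test_that("alignment scores agree with an independent Gotoh DP", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(17)
  for (i in 1:50) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    got <- global_align(a, b)$score
    exp <- oracle_global_score(a, b, BLOSUM62)
    expect_equal(got, exp, info = paste("pair", i))
  }
})

test_that("identity uses the both-non-gap column denominator", {
  expect_equal(unname(pairwise_identity(c(a = "ACDE", b = "ACDE"),
                                        aligned = TRUE)["a", "b"]), 100)
  expect_equal(unname(pairwise_identity(c(a = "ACDE", b = "ACDF"),
                                        aligned = TRUE)["a", "b"]), 75)
  # the gapped column is excluded from the denominator
  expect_equal(unname(pairwise_identity(c(a = "AC-E", b = "ACDE"),
                                        aligned = TRUE)["a", "b"]), 100)
  expect_warning(
    m <- pairwise_identity(c(a = "AB--", b = "--CD"), aligned = TRUE),
    "co-occupied")
  expect_equal(unname(m["a", "b"]), 0)
  expect_error(pairwise_identity(c(a = "ACD", b = "AC"), aligned = TRUE),
               "unequal")
})

test_that("identity matrices are symmetric, 100 on the diagonal, and
           permutation-equivariant", {
  set.seed(23)
  seqs <- setNames(replicate(5, random_protein(40)), paste0("s", 1:5))
  m <- pairwise_identity(seqs, aligned = TRUE)
  expect_true(isSymmetric(unname(m)))
  expect_equal(unname(diag(m)), rep(100, 5))
  expect_true(all(m >= 0 & m <= 100))
  perm <- c(3, 1, 5, 2, 4)
  m2 <- pairwise_identity(seqs[perm], aligned = TRUE)
  expect_equal(m2, m[perm, perm])
})

test_that("clade clustering is single linkage at the identity threshold", {
  ids <- paste0("v", 1:6)
  m <- matrix(5, 6, 6, dimnames = list(ids, ids))
  diag(m) <- 100
  m[1:3, 1:3] <- 40; m[4:6, 4:6] <- 40; diag(m) <- 100
  cl <- cluster_clades(m, threshold_pct = 15)
  expect_equal(length(unique(cl$clade)), 2L)
  expect_equal(length(unique(cl$clade[1:3])), 1L)
  expect_equal(length(unique(cl$clade[4:6])), 1L)

  # all below threshold: all singletons
  m2 <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m2) <- 100
  expect_equal(length(unique(cluster_clades(m2, 15)$clade)), 4L)

  # labels ordered by clade size, ties by smallest member id
  m3 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m3[1:2, 1:2] <- 50; m3[3:5, 3:5] <- 50; diag(m3) <- 100
  cl3 <- cluster_clades(m3, 15)
  expect_equal(cl3$clade[3], "clade_1")   # the 3-member clade
  expect_equal(cl3$clade[1], "clade_2")
})

test_that("clade components match a BFS oracle and shrink monotonically", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    m <- matrix(runif(n * n, 0, 40), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 100
    dimnames(m) <- list(paste0("x", 1:n), paste0("x", 1:n))
    thr <- runif(1, 5, 35)
    cl <- cluster_clades(m, thr)
    comp <- oracle_components(m, thr)
    # same partition: clade labels and BFS components co-classify all pairs
    got <- outer(cl$clade, cl$clade, "==")
    exp <- outer(comp, comp, "==")
    expect_true(all(got == exp), info = paste("matrix", i))
  }
  # lowering the threshold never increases the clade count
  set.seed(32)
  n <- 10
  m <- matrix(runif(n * n, 0, 50), n, n); m <- (m + t(m)) / 2; diag(m) <- 100
  dimnames(m) <- list(paste0("x", 1:n), paste0("x", 1:n))
  counts <- vapply(c(40, 30, 20, 10, 5), function(t)
    length(unique(cluster_clades(m, t)$clade)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
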