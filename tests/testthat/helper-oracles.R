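# Independent oracles used by the property tests. Each re-derives the
# expected result by a different route than the implementation under test.

# --- six-frame ORF enumeration by inter-stop segment analysis ---------------
oracle_orfs <- function(seq, require_atg = TRUE, min_aa = 1L) {
  code <- Biostrings::GENETIC_CODE
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  rows <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    for (f in 0:2) {
      n <- (nchar(s) - f) %/% 3L
      if (n < 1L) next
      st <- f + 3L * (0:(n - 1L))
      cod <- substring(s, st + 1L, st + 3L)
      aa <- unname(code[cod])                       # NA for N codons
      term <- which(is.na(aa) | aa == "*")
      bounds <- c(0L, term, n + 1L)
      emit <- function(i, j, c5, c3) {
        prot <- paste(aa[i:j], collapse = "")
        if (nchar(prot) < min_aa) return()
        w_start <- st[i]
        w_end <- st[j] + 3L + if (c3) 3L else 0L
        if (strand == "-") {
          tmp <- w_start; w_start <- L - w_end; w_end <- L - tmp
        }
        rows[[length(rows) + 1L]] <<- data.frame(
          strand = strand, frame = f, start = w_start, end = w_end,
          protein = prot, complete5 = c5, complete3 = c3,
          stringsAsFactors = FALSE)
      }
      for (b in seq_len(length(bounds) - 1L)) {
        a <- bounds[b] + 1L
        z <- bounds[b + 1L] - 1L
        if (a > z) next                              # empty segment
        leading <- (b == 1L)
        stopped <- (bounds[b + 1L] <= n) && !is.na(aa[bounds[b + 1L]]) &&
          aa[bounds[b + 1L]] == "*"
        atg <- which(cod[a:z] == "ATG")
        atg <- if (length(atg)) a + atg[1L] - 1L else NA_integer_
        if (!require_atg) {
          emit(a, z, cod[a] == "ATG", stopped)
        } else if (leading) {
          emit(a, z, cod[a] == "ATG", stopped)
          if (cod[a] != "ATG" && !is.na(atg)) emit(atg, z, TRUE, stopped)
        } else if (!is.na(atg)) {
          emit(atg, z, TRUE, stopped)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      protein = character(0), complete5 = logical(0),
                      complete3 = logical(0)))
  }
  do.call(rbind, rows)
}

orf_key <- function(df) {
  sort(paste(df$strand, df$start, df$end, df$protein, df$complete5,
             df$complete3, sep = "|"))
}

# --- Gotoh global alignment, score only (cost of a length-k gap:
#     gap_open + k * gap_extend, matching the convention under test) --------
oracle_global_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  open <- gap_open + gap_extend
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in b (x aligned to -)
  Y <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in a
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(gap_open + gap_extend * i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(gap_open + gap_extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[x[i], y[j]]
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open, X[i, j + 1L] - gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open, Y[i + 1L, j] - gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# --- connected components by breadth-first search ---------------------------
oracle_components <- function(mat, threshold) {
  n <- nrow(mat)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(mat[v, ] >= threshold & is.na(comp))
      nb <- setdiff(nb, v)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

# --- textbook Pearson correlation from raw sums -----------------------------
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","E","Q","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal single-end SAM record
sam_line <- function(qname, flag, rname, pos = 1L, seq = "ACGT") {
  paste(qname, flag, rname, pos, 60, paste0(nchar(seq), "M"), "*", 0, 0,
        seq, "*", sep = "\t")
}

study_file <- function(name) {
  system.file("extdata", name, package = "orfanscan", mustWork = TRUE)
}
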