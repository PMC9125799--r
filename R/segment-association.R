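#' Terminal sequence conservation between two genome segments
#'
#' Bisegmented RNA viruses carry near-identical 5' and 3' termini on both
#' segments. Counts position-by-position mismatches over the first `k` and
#' the last `k` nucleotides of two plus-sense sequences — no alignment, no
#' shifts.
#'
#' @param seqA,seqB Nucleotide strings, both at least `k` nt, both in
#'   plus-sense (coding) orientation.
#' @param k Terminal window length in nt (default 20).
#' @return A list with `k`, `mism5` and `mism3` (mismatch counts, each in
#'   `[0, k]`).
#' @export
terminal_conservation <- function(seqA, seqB, k = 20L) {
  if (nchar(seqA) < k || nchar(seqB) < k) {
    stop("both sequences must be at least k = ", k, " nt long")
  }
  mism <- function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1L]] !=
        strsplit(y, "", fixed = TRUE)[[1L]])
  }
  list(k = as.integer(k),
       mism5 = mism(substr(seqA, 1L, k), substr(seqB, 1L, k)),
       mism3 = mism(substr(seqA, nchar(seqA) - k + 1L, nchar(seqA)),
                    substr(seqB, nchar(seqB) - k + 1L, nchar(seqB))))
}

#' Binarize a Ct table into presence/absence
#'
#' A sample is scored positive for an assay when its Ct is at or below
#' `cutoff`; Ct above the cutoff, or a blank cell (`NA`), is negative.
#'
#' @param ct Numeric Ct matrix from [read_ct_table()].
#' @param cutoff Ct cutoff (default 38: values above 38 are negative).
#' @return Logical matrix of the same shape: `TRUE` = present.
#' @export
binarize_ct <- function(ct, cutoff = 38.0) {
  pres <- !is.na(ct) & ct <= cutoff
  dimnames(pres) <- dimnames(ct)
  pres
}

#' Co-occurrence of two segments across samples
#'
#' @param presA,presB Logical presence vectors over the same named sample
#'   set.
#' @return A list with `jaccard` (`|A∩B| / |A∪B|`, 0 with a warning when
#'   both sets are empty), `exact` (identical presence sets) and
#'   `n_shared_positive`.
#' @export
cooccurrence_score <- function(presA, presB) {
  if (length(presA) != length(presB)) {
    stop("presence vectors cover different sample sets")
  }
  if (!is.null(names(presA)) && !is.null(names(presB)) &&
      !identical(names(presA), names(presB))) {
    stop("presence vectors cover different sample sets")
  }
  inter <- sum(presA & presB)
  union <- sum(presA | presB)
  if (union == 0L) {
    warning("both presence sets empty; Jaccard defined as 0")
    jac <- 0
  } else {
    jac <- inter / union
  }
  list(jaccard = jac, exact = all(presA == presB),
       n_shared_positive = as.integer(inter))
}

#' Cross-library abundance correlation between two segments
#'
#' Pearson correlation of `log10(count + 1)` across libraries; read counts
#' span orders of magnitude, so the log scale is what "correlate
#' quantitatively" means here. Libraries where both segments have zero reads
#' are dropped first. The correlation is undefined (`NA`) when fewer than 3
#' libraries remain or either transformed vector is constant (with a
#' warning).
#'
#' @param countsA,countsB Non-negative read-count vectors over the same
#'   library set.
#' @return A list with `r` and `n_libraries_used`.
#' @export
abundance_correlation <- function(countsA, countsB) {
  if (length(countsA) != length(countsB)) {
    stop("count vectors cover different library sets")
  }
  use <- !(countsA == 0 & countsB == 0)
  a <- log10(countsA[use] + 1)
  b <- log10(countsB[use] + 1)
  n <- sum(use)
  if (n < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    if (n >= 3L) warning("constant abundance vector; correlation undefined")
    return(list(r = NA_real_, n_libraries_used = as.integer(n)))
  }
  list(r = stats::cor(a, b), n_libraries_used = as.integer(n))
}

#' Default association rule thresholds
#'
#' STRONG evidence: both termini conserved (`mism5 <= 2` and `mism3 <= 2` at
#' `k = 20`). MODERATE: exact presence/absence co-occurrence with at least
#' `min_shared` shared positives. WEAK: abundance correlation `r >= r_min`
#' over at least `min_libs` libraries. A pair is `associated` when it has at
#' least one STRONG line of evidence, or at least two of
#' {MODERATE, WEAK}.
#'
#' @param k Terminal window (nt).
#' @param max_mism5,max_mism3 Maximum terminal mismatches for STRONG.
#' @param min_shared Minimum shared positive samples for MODERATE.
#' @param r_min,min_libs Correlation threshold and minimum libraries for
#'   WEAK.
#' @return A named list of thresholds, echoed verbatim into reports.
#' @export
association_rules <- function(k = 20L, max_mism5 = 2L, max_mism3 = 2L,
                              min_shared = 2L, r_min = 0.9, min_libs = 3L) {
  list(k = k, max_mism5 = max_mism5, max_mism3 = max_mism3,
       min_shared = min_shared, r_min = r_min, min_libs = min_libs)
}

#' Combine evidence streams into an association call for one segment pair
#'
#' @param rna1_id,rna2_id Segment ids (for the report row).
#' @param terminal List from [terminal_conservation()], or `NULL` if not
#'   computed.
#' @param cooccurrence List from [cooccurrence_score()], or `NULL`.
#' @param correlation List from [abundance_correlation()], or `NULL`.
#' @param rules Thresholds from [association_rules()].
#' @return A one-row data.frame: ids, the evidence values, the per-stream
#'   verdicts (`strong`, `moderate`, `weak`) and `call`
#'   (`"associated"`/`"unresolved"`).
#' @export
call_association <- function(rna1_id, rna2_id, terminal = NULL,
                             cooccurrence = NULL, correlation = NULL,
                             rules = association_rules()) {
  if (is.null(terminal) && is.null(cooccurrence) && is.null(correlation)) {
    stop("at least one evidence stream is required")
  }
  strong <- !is.null(terminal) &&
    terminal$mism5 <= rules$max_mism5 && terminal$mism3 <= rules$max_mism3
  moderate <- !is.null(cooccurrence) && isTRUE(cooccurrence$exact) &&
    cooccurrence$n_shared_positive >= rules$min_shared
  weak <- !is.null(correlation) && !is.na(correlation$r) &&
    correlation$r >= rules$r_min &&
    correlation$n_libraries_used >= rules$min_libs
  call <- if (strong || (moderate + weak >= 2L)) "associated" else "unresolved"
  data.frame(
    rna1_id = rna1_id, rna2_id = rna2_id,
    mism5 = if (is.null(terminal)) NA_integer_ else terminal$mism5,
    mism3 = if (is.null(terminal)) NA_integer_ else terminal$mism3,
    jaccard = if (is.null(cooccurrence)) NA_real_ else cooccurrence$jaccard,
    exact_cooccurrence = if (is.null(cooccurrence)) NA else cooccurrence$exact,
    n_shared_positive = if (is.null(cooccurrence)) NA_integer_
                        else cooccurrence$n_shared_positive,
    abundance_r = if (is.null(correlation)) NA_real_ else correlation$r,
    n_libraries = if (is.null(correlation)) NA_integer_
                  else correlation$n_libraries_used,
    strong = strong, moderate = moderate, weak = weak, call = call,
    stringsAsFactors = FALSE)
}

#' Score all RNA1 x RNA2 candidate pairs
#'
#' Runs the three evidence streams for every pair of an RdRP segment and a
#' companion-segment candidate, using whichever inputs are available:
#' sequences (terminal conservation), a binarized Ct matrix (co-occurrence),
#' and per-library counts (abundance correlation).
#'
#' @param rna1_ids,rna2_ids Character vectors of segment ids.
#' @param seqs Named character vector of plus-sense nucleotide sequences
#'   (may be `NULL`).
#' @param presence Logical presence matrix (segments x samples) from
#'   [binarize_ct()] (may be `NULL`).
#' @param counts Numeric count matrix (segments x libraries) (may be
#'   `NULL`).
#' @param rules Thresholds from [association_rules()].
#' @return A data.frame with one row per pair, as in [call_association()].
#' @export
associate_segments <- function(rna1_ids, rna2_ids, seqs = NULL,
                               presence = NULL, counts = NULL,
                               rules = association_rules()) {
  rows <- list()
  for (r1 in rna1_ids) {
    for (r2 in rna2_ids) {
      term <- cooc <- corr <- NULL
      if (!is.null(seqs) && r1 %in% names(seqs) && r2 %in% names(seqs)) {
        term <- terminal_conservation(seqs[[r1]], seqs[[r2]], k = rules$k)
      }
      if (!is.null(presence) && all(c(r1, r2) %in% rownames(presence))) {
        cooc <- cooccurrence_score(presence[r1, ], presence[r2, ])
      }
      if (!is.null(counts) && all(c(r1, r2) %in% rownames(counts))) {
        corr <- suppressWarnings(
          abundance_correlation(counts[r1, ], counts[r2, ]))
      }
      if (is.null(term) && is.null(cooc) && is.null(corr)) next
      rows[[length(rows) + 1L]] <-
        call_association(r1, r2, term, cooc, corr, rules)
    }
  }
  if (length(rows) == 0L) {
    return(call_association("x", "y",
                            terminal = list(k = 0, mism5 = 99, mism3 = 99),
                            rules = rules)[0, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
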