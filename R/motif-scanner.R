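# split an MSA (named character vector of equal-length gapped rows) into a
# character matrix, rows = sequences, columns = alignment columns
.msa_matrix <- function(msa) {
  if (length(unique(nchar(msa))) > 1L) stop("ragged MSA: rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  mat
}

#' Locate palm-domain motif anchors A, B and C in an RdRP protein alignment
#'
#' Searches for the conserved architecture of the RdRP palm domain: a
#' conserved aspartate column (motif A), downstream a pair of conserved
#' glycine columns (motif B), and further downstream the central aspartate
#' of the catalytic motif C. A column is "conserved" for a residue when the
#' fraction of rows carrying it is at least `min_frac` (gaps count against).
#' Among all column triples satisfying the spacing constraints
#' (`colB1 - colA >= min_AB_gap`, `colC - colB2 >= min_BC_gap`,
#' `colA < colB1 <= colB2 < colC`), the motif-C column with the highest
#' D-frequency wins; ties break toward the smallest column index. The two
#' glycines may be adjacent or up to `max_B_span` columns apart, preferring
#' adjacent pairs. When no candidate reaches `min_frac` a no-anchor result
#' (`found = FALSE`) is returned rather than an error.
#'
#' @param msa Named character vector: rows of one protein alignment
#'   (`-` = gap), at least 2 rows.
#' @param min_frac Minimum conservation fraction per anchor column
#'   (default 0.7).
#' @param min_AB_gap Minimum columns between motif A and the first motif-B
#'   glycine (default 20).
#' @param min_BC_gap Minimum columns between the second motif-B glycine and
#'   motif C (default 5).
#' @param max_B_span Maximum distance between the two glycine columns
#'   (default 3; 1 = adjacent).
#' @return A list with `found`, and when found: `colA`, `colB` (length-2
#'   integer), `colC` (1-based alignment columns) and `support` (named
#'   conservation fractions). Parameters are echoed in `params`.
#' @export
locate_motif_anchors <- function(msa, min_frac = 0.7, min_AB_gap = 20L,
                                 min_BC_gap = 5L, max_B_span = 3L) {
  if (length(msa) < 2L) stop("need at least 2 aligned sequences")
  mat <- .msa_matrix(msa)
  n <- nrow(mat)
  d_frac <- colMeans(mat == "D")
  g_frac <- colMeans(mat == "G")
  params <- list(min_frac = min_frac, min_AB_gap = min_AB_gap,
                 min_BC_gap = min_BC_gap, max_B_span = max_B_span)
  no_anchor <- list(found = FALSE, params = params)
  d_cols <- which(d_frac >= min_frac)
  g_cols <- which(g_frac >= min_frac)
  if (length(d_cols) < 2L || length(g_cols) < 2L) return(no_anchor)
  # candidate glycine pairs, adjacent preferred, then by position
  pairs <- list()
  for (span in seq_len(max_B_span)) {
    b1 <- g_cols[(g_cols + span) %in% g_cols]
    for (x in b1) pairs[[length(pairs) + 1L]] <- c(x, x + span)
  }
  if (length(pairs) == 0L) return(no_anchor)
  valid_c <- integer(0)
  for (cc in d_cols) {
    ok <- FALSE
    for (p in pairs) {
      if (cc - p[2L] < min_BC_gap) next
      if (any(d_cols < p[1L] & p[1L] - d_cols >= min_AB_gap)) {
        ok <- TRUE
        break
      }
    }
    if (ok) valid_c <- c(valid_c, cc)
  }
  if (length(valid_c) == 0L) return(no_anchor)
  best <- max(d_frac[valid_c])
  colC <- min(valid_c[d_frac[valid_c] >= best])   # tie -> smallest column
  # deterministic choice of B and A for the chosen C: adjacent-preferred,
  # smallest-position glycine pair that admits an upstream A; smallest A
  colB <- NULL
  for (p in pairs) {
    if (colC - p[2L] < min_BC_gap) next
    a_ok <- d_cols[d_cols < p[1L] & p[1L] - d_cols >= min_AB_gap]
    if (length(a_ok) > 0L) {
      colB <- p
      colA <- min(a_ok)
      break
    }
  }
  list(found = TRUE, colA = colA, colB = colB, colC = colC,
       support = c(A = unname(d_frac[colA]), B1 = unname(g_frac[colB[1L]]),
                   B2 = unname(g_frac[colB[2L]]), C = unname(d_frac[colC])),
       params = params)
}

#' Extract per-sequence catalytic triads at motif C
#'
#' The triad is the three residues at alignment columns
#' `(colC - 1, colC, colC + 1)`; gaps are rendered `-` and make the call
#' `incomplete`. Complete triads are classified with [classify_triad()] and
#' tallied.
#'
#' @param msa Named character vector of aligned rows.
#' @param anchors Anchor list from [locate_motif_anchors()] (or a list with
#'   at least `colC`), with `colC` not at an alignment edge.
#' @param catalog Passed to [classify_triad()].
#' @return A list with `calls` (data.frame `seq_id`, `triad`, `status`),
#'   `tally` (named counts over complete triads) and `mode` (most common
#'   complete triad, smallest alphabetically on ties; `NA` if none).
#' @export
extract_triads <- function(msa, anchors,
                           catalog = list(canonical = "GDD",
                                          known_rare = c("SDD", "GDN"))) {
  mat <- .msa_matrix(msa)
  colC <- anchors$colC
  if (is.null(colC)) stop("anchors must contain colC")
  if (colC - 1L < 1L || colC + 1L > ncol(mat)) {
    stop("motif-C column at alignment edge: anchor invalid")
  }
  triads <- apply(mat[, (colC - 1L):(colC + 1L), drop = FALSE], 1L,
                  paste, collapse = "")
  status <- vapply(triads, function(t) {
    if (grepl("-", t, fixed = TRUE)) "incomplete"
    else classify_triad(t, catalog)
  }, character(1), USE.NAMES = FALSE)
  calls <- data.frame(seq_id = rownames(mat), triad = unname(triads),
                      status = status, row.names = NULL,
                      stringsAsFactors = FALSE)
  complete <- calls$triad[calls$status != "incomplete"]
  tally <- if (length(complete)) table(complete) else table(character(0))
  tally <- stats::setNames(as.integer(tally), names(tally))
  mode <- if (length(tally)) {
    cand <- names(tally)[tally == max(tally)]
    sort(cand)[1L]
  } else NA_character_
  list(calls = calls, tally = tally, mode = mode)
}

#' Classify a catalytic triad against a catalog
#'
#' `GDD` is the canonical RdRP motif-C triad; `SDD` (many negative-sense RNA
#' viruses) and `GDN` are the classical rare alternatives. Anything else
#' complete is `novel` — e.g. the NDD, ADD, HDD and GDQ triads carried by
#' highly divergent mycovirus RdRPs.
#'
#' @param triad 3-character residue string.
#' @param catalog List with elements `canonical` (single triad) and
#'   `known_rare` (character vector).
#' @return One of `"canonical"`, `"known_rare"`, `"novel"`.
#' @export
classify_triad <- function(triad,
                           catalog = list(canonical = "GDD",
                                          known_rare = c("SDD", "GDN"))) {
  if (!is.character(triad) || length(triad) != 1L || nchar(triad) != 3L) {
    stop("triad must be a single 3-character string")
  }
  if (triad == catalog$canonical) "canonical"
  else if (triad %in% catalog$known_rare) "known_rare"
  else "novel"
}

#' Cross-tabulate triads by clade
#'
#' Joins triad calls with a clade assignment, making statements like "this
#' triad is exclusive to one clade" computable.
#'
#' @param calls data.frame from [extract_triads()]`$calls`.
#' @param clades data.frame from [cluster_clades()] (`id`, `clade`).
#' @return A contingency table (triad x clade) over complete triads.
#' @export
triads_by_clade <- function(calls, clades) {
  merged <- merge(calls, clades, by.x = "seq_id", by.y = "id")
  merged <- merged[merged$status != "incomplete", , drop = FALSE]
  table(triad = merged$triad, clade = merged$clade)
}

#' Render an annotated alignment marking motif anchor columns
#'
#' Produces a plain-text block: one line per sequence plus a marker line
#' with `A`, `B` and `C` under the anchor columns.
#'
#' @param msa Named character vector of aligned rows.
#' @param anchors Anchor list from [locate_motif_anchors()].
#' @return Character vector of text lines, invisibly printable via
#'   `writeLines`.
#' @export
annotate_alignment <- function(msa, anchors) {
  if (!isTRUE(anchors$found)) stop("no anchors to annotate")
  width <- nchar(msa[[1L]])
  marker <- rep(" ", width)
  marker[anchors$colA] <- "A"
  marker[anchors$colB] <- "B"
  marker[anchors$colC] <- "C"
  namew <- max(nchar(names(msa))) + 2L
  c(paste0(formatC("", width = namew), paste(marker, collapse = "")),
    vapply(names(msa), function(id)
      paste0(formatC(id, width = namew, flag = "-"), msa[[id]]),
      character(1), USE.NAMES = FALSE))
}
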