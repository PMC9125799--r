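#' Global pairwise protein alignment (affine gaps)
#'
#' End-to-end Needleman–Wunsch alignment with affine gap penalties, used as
#' the self-contained fallback when no multiple sequence alignment is
#' supplied. Backed by [Biostrings::pairwiseAlignment()] with BLOSUM62 by
#' default.
#'
#' @param a,b Protein sequences (non-empty strings).
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap opening/extension penalties (positive).
#' @return A list with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length), `score`, and `identity_pct` computed over columns where both
#'   sequences carry a residue.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  list(aligned_a = pa, aligned_b = pb, score = Biostrings::score(al),
       identity_pct = .column_identity(pa, pb))
}

# percent identity over columns where both rows are non-gap
.column_identity <- function(ra, rb) {
  ca <- strsplit(ra, "", fixed = TRUE)[[1L]]
  cb <- strsplit(rb, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) stop("aligned rows of unequal length")
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(NA_real_)
  100 * sum(ca[both] == cb[both]) / sum(both)
}

#' Pairwise percent-identity matrix over proteins
#'
#' In MSA mode (`aligned = TRUE`) all sequences must have equal column
#' counts; identity between two rows is `100 x matches / columns where both
#' rows carry a residue`. Pairs with zero co-occupied columns get identity 0
#' with a warning. In fallback mode each pair is aligned globally with
#' [global_align()] first.
#'
#' @param seqs Named character vector of protein sequences (gapped when
#'   `aligned = TRUE`).
#' @param aligned `TRUE` if `seqs` are rows of one multiple alignment.
#' @param ... Passed to [global_align()] in fallback mode.
#' @return A symmetric numeric matrix in `[0, 100]` with 100 on the
#'   diagonal, dimnames = sequence ids.
#' @export
pairwise_identity <- function(seqs, aligned = FALSE, ...) {
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  if (aligned && length(unique(nchar(seqs))) > 1L) {
    stop("MSA rows of unequal length")
  }
  mat <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(mat)
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (aligned) {
        idn <- .column_identity(seqs[[i]], seqs[[j]])
      } else {
        idn <- global_align(gsub("-", "", seqs[[i]], fixed = TRUE),
                            gsub("-", "", seqs[[j]], fixed = TRUE), ...)$identity_pct
      }
      if (is.na(idn)) {
        idn <- 0
        warned <- TRUE
      }
      mat[i, j] <- mat[j, i] <- idn
    }
  }
  if (warned) {
    warning("some pairs share no co-occupied columns; identity set to 0")
  }
  mat
}

#' Cluster sequences into clades by single linkage on percent identity
#'
#' Builds a graph with an edge wherever pairwise identity is at or above
#' `threshold_pct` and returns its connected components. Labels
#' `clade_1 ... clade_k` are assigned by descending clade size, ties broken
#' by the lexicographically smallest member id; singletons are allowed.
#'
#' @param mat Symmetric identity matrix from [pairwise_identity()].
#' @param threshold_pct Edge threshold in percent (default 15, between
#'   typical inter-group and intra-group identities of highly divergent
#'   RdRP clades).
#' @return A data.frame with columns `id` and `clade`.
#' @export
cluster_clades <- function(mat, threshold_pct = 15.0) {
  if (!isSymmetric(unname(mat))) stop("identity matrix must be symmetric")
  adj <- (mat >= threshold_pct)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  ids <- rownames(mat)
  members <- split(ids, comp$membership)
  # order components: size desc, then smallest member id
  ord <- order(-lengths(members),
               vapply(members, function(m) sort(m)[1L], character(1)))
  label <- character(length(ids))
  for (k in seq_along(ord)) {
    label[ids %in% members[[ord[k]]]] <- paste0("clade_", k)
  }
  data.frame(id = ids, clade = label, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write an identity matrix as TSV (ids x ids, one decimal)
#'
#' @param mat Identity matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(mat, path) {
  chr <- formatC(mat, format = "f", digits = 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(mat)), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], chr[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Heatmap of an identity matrix
#'
#' Thin convenience wrapper around [pheatmap::pheatmap()] (suggested
#' dependency).
#'
#' @param mat Identity matrix.
#' @param ... Passed to `pheatmap`.
#' @return The pheatmap object, invisibly.
#' @export
plot_identity_matrix <- function(mat, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_identity_matrix requires the 'pheatmap' package")
  }
  invisible(pheatmap::pheatmap(mat, cluster_rows = FALSE,
                               cluster_cols = FALSE, ...))
}
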