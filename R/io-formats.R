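#' Read contigs from a FASTA file
#'
#' Reads nucleotide records, uppercases the sequences, removes line wrapping,
#' and replaces any character outside `A, C, G, T, N` (e.g. IUPAC ambiguity
#' codes) by `N` with a warning. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `seq` and `length` (nt), one row
#'   per record, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " record(s) contained characters outside {A,C,G,T,N}; ",
            "replaced by N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  data.frame(id = unname(ids), seq = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write contigs to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, path))` is the
#' identity on `(id, seq)` pairs.
#'
#' @param contigs A data.frame with columns `id` and `seq` (nucleotide), or a
#'   named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  if (is.data.frame(contigs)) {
    seqs <- stats::setNames(contigs$seq, contigs$id)
  } else {
    seqs <- contigs
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read protein sequences (possibly gapped) from FASTA
#'
#' Used for protein FASTA and for multiple sequence alignments in aligned
#' FASTA, where `-` marks a gap. No alphabet rewriting is applied beyond
#' uppercasing.
#'
#' @param path Path to a (aligned) protein FASTA file.
#' @return A named character vector of uppercase sequences, in file order.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  stats::setNames(unname(seqs), ids)
}

#' Read a BLAST/DIAMOND tabular hits file and collect hit query ids
#'
#' Parses the standard 12-column tabular dialect ("outfmt 6"): field 1 is the
#' query id, field 2 the subject id, field 11 the e-value, field 12 the bit
#' score. Returns the set of query ids having at least one hit at or below
#' `evalue_max`; these are the contigs that are *not* ORFans. Lines with fewer
#' than 12 fields are counted and reported with a warning.
#'
#' @param path Path to the tabular hits file.
#' @param evalue_max Maximum e-value for a hit to count (default `1e-3`; the
#'   cutoff for calling a contig "matched" is deliberately explicit).
#' @return Character vector: the unique query ids with a qualifying hit.
#'   An empty file yields `character(0)`.
#' @export
read_hits_table <- function(path, evalue_max = 1e-3) {
  if (!file.exists(path)) {
    stop("hits table not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(character(0))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  malformed <- nf < 12L
  if (any(malformed)) {
    warning(sum(malformed), " malformed line(s) (fewer than 12 columns) ",
            "skipped in ", path)
    fields <- fields[!malformed]
    lineno <- which(!malformed)
  } else {
    lineno <- seq_along(fields)
  }
  if (length(fields) == 0L) {
    return(character(0))
  }
  qid <- vapply(fields, `[[`, character(1), 1L)
  eval_chr <- vapply(fields, `[[`, character(1), 11L)
  evalue <- suppressWarnings(as.numeric(eval_chr))
  if (anyNA(evalue)) {
    bad <- which(is.na(evalue))[1L]
    stop("unparseable e-value '", eval_chr[bad], "' at line ", lineno[bad],
         " of ", path)
  }
  unique(qid[evalue <= evalue_max])
}

# SAM flag bits used below
.FLAG_PAIRED <- 0x1
.FLAG_UNMAPPED <- 0x4
.FLAG_REVERSE <- 0x10
.FLAG_FIRST <- 0x40
.FLAG_SECONDARY <- 0x100
.FLAG_SUPPLEMENTARY <- 0x800

#' Read stranded alignments from a SAM text file
#'
#' Only the fields the pipeline uses are consumed: read name, FLAG, and
#' reference name. Header lines (`@`) are skipped. Secondary (0x100) and
#' supplementary (0x800) records are dropped so each read is counted once;
#' unmapped records (0x4) are returned with `is_mapped = FALSE` and must be
#' ignored by downstream tallies. Orientation comes from flag bit 0x10;
#' pairing from 0x1/0x40 (`is_first_in_pair` is `NA` for single-end reads).
#'
#' @param path Path to a SAM text file (BAM is not accepted).
#' @return A data.frame with columns `read_id`, `ref_id`, `is_mapped`,
#'   `is_reverse` (NA when unmapped) and `is_first_in_pair` (NA when
#'   single-end).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) {
    stop("SAM file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  if (length(body) == 0L) {
    return(data.frame(read_id = character(0), ref_id = character(0),
                      is_mapped = logical(0), is_reverse = logical(0),
                      is_first_in_pair = logical(0)))
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- body[which(nf < 11L)[1L]]
    stop("truncated SAM record (fewer than 11 fields) at line ", bad,
         " of ", path)
  }
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(flag)) {
    bad <- body[which(is.na(flag))[1L]]
    stop("unparseable FLAG at line ", bad, " of ", path)
  }
  keep <- bitwAnd(flag, .FLAG_SECONDARY) == 0L &
    bitwAnd(flag, .FLAG_SUPPLEMENTARY) == 0L
  fields <- fields[keep]
  flag <- flag[keep]
  read_id <- vapply(fields, `[[`, character(1), 1L)
  ref_id <- vapply(fields, `[[`, character(1), 3L)
  is_mapped <- bitwAnd(flag, .FLAG_UNMAPPED) == 0L
  is_reverse <- ifelse(is_mapped, bitwAnd(flag, .FLAG_REVERSE) != 0L, NA)
  paired <- bitwAnd(flag, .FLAG_PAIRED) != 0L
  is_first <- ifelse(paired, bitwAnd(flag, .FLAG_FIRST) != 0L, NA)
  data.frame(read_id = read_id, ref_id = ref_id, is_mapped = is_mapped,
             is_reverse = is_reverse, is_first_in_pair = is_first,
             stringsAsFactors = FALSE)
}

#' Read a qPCR Ct table
#'
#' Rows are assay/segment ids (header column), columns are sample/isolate ids
#' (header row). Decimal commas are accepted (`"24,67"` is read as 24.67), as
#' printed in many European-locale qPCR exports; blank cells become `NA`
#' (meaning: no amplification / negative). The field delimiter is sniffed
#' from the header line (tab or semicolon) unless given.
#'
#' @param path Path to the delimited Ct table.
#' @param sep Field separator; `NULL` (default) sniffs `"\t"` vs `";"`.
#' @return A numeric matrix (rows = assays, columns = samples) with `NA` for
#'   blank cells. All non-missing values are positive.
#' @export
read_ct_table <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop("Ct table not found: ", path)
  }
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(";", header, fixed = TRUE)) ";" else "\t"
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "", fill = TRUE)
  mat <- as.matrix(raw)
  out <- matrix(NA_real_, nrow = nrow(mat), ncol = ncol(mat),
                dimnames = dimnames(mat))
  nonblank <- !is.na(mat) & nzchar(trimws(mat))
  vals <- suppressWarnings(as.numeric(sub(",", ".", mat[nonblank], fixed = TRUE)))
  if (anyNA(vals)) {
    bad <- which(nonblank, arr.ind = TRUE)[which(is.na(vals))[1L], ]
    stop("non-numeric Ct value '", mat[bad[1L], bad[2L]], "' at row '",
         rownames(mat)[bad[1L]], "', column '", colnames(mat)[bad[2L]], "'")
  }
  if (any(vals <= 0)) {
    stop("Ct values must be positive")
  }
  out[nonblank] <- vals
  out
}

#' Write a qPCR Ct table
#'
#' Inverse of [read_ct_table()] for tables written with dot decimals:
#' `read_ct_table(write_ct_table(m, path))` reproduces `m`. `NA` cells are
#' written blank.
#'
#' @param ct Numeric matrix with row and column names.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, sep = "\t") {
  chr <- ifelse(is.na(ct), "", format(ct, trim = TRUE, scientific = FALSE))
  dim(chr) <- dim(ct)
  dimnames(chr) <- dimnames(ct)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(ct)), collapse = sep), con)
  for (i in seq_len(nrow(ct))) {
    writeLines(paste(c(rownames(ct)[i], chr[i, ]), collapse = sep), con)
  }
  invisible(path)
}

#' Read a per-library stranded read-count table
#'
#' Parses tables shaped like the study's per-segment mapping summaries: one
#' row per genome segment, a `length` column, then per-library column triplets
#' `<lib>`, `<lib>pos`, `<lib>neg` holding the total, plus-sense and
#' minus-sense read counts. Thousands-separator commas inside integers
#' (`"132,412"`) are stripped. Libraries differ between rows in the printed
#' tables; cells absent for a row are returned as `NA`.
#'
#' @param path Path to a tab-separated counts table with a header row whose
#'   first column holds segment ids.
#' @return A long data.frame with columns `segment_id`, `library_id`,
#'   `total`, `plus`, `minus` (one row per segment x library).
#' @export
read_strand_counts <- function(path) {
  if (!file.exists(path)) {
    stop("counts table not found: ", path)
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           strip.white = TRUE)
  seg <- raw[[1L]]
  cols <- colnames(raw)[-1L]
  libcols <- setdiff(cols, c("length"))
  base <- unique(sub("(pos|neg)$", "", libcols))
  num <- function(x) {
    x <- gsub(",(?=\\d{3}(\\D|$))", "", x, perl = TRUE)  # thousands commas
    suppressWarnings(as.numeric(x))
  }
  out <- do.call(rbind, lapply(base, function(lib) {
    tot <- if (lib %in% cols) num(raw[[lib]]) else NA_real_
    pos <- if (paste0(lib, "pos") %in% cols) num(raw[[paste0(lib, "pos")]]) else NA_real_
    neg <- if (paste0(lib, "neg") %in% cols) num(raw[[paste0(lib, "neg")]]) else NA_real_
    data.frame(segment_id = seg, library_id = lib, total = tot,
               plus = pos, minus = neg, stringsAsFactors = FALSE)
  }))
  out[order(match(out$segment_id, seg)), , drop = FALSE]
}
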