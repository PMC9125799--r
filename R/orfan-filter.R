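# Average (not monoisotopic) residue masses in Daltons, Expasy convention.
# Protein mass = sum of residue masses + one water.
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0513,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.0153

#' Average molecular mass of a protein
#'
#' Sums standard average residue masses and adds one water (18.0153 Da).
#' `X` (unknown residue) contributes the unweighted mean of the 20 standard
#' residue masses.
#'
#' @param protein Amino-acid string over the 20-letter alphabet plus `X`.
#' @return Mass in Daltons.
#' @examples
#' protein_mass("G")   # 75.0666
#' @export
protein_mass <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein)) {
    stop("protein must be a non-empty string")
  }
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  masses <- c(.RESIDUE_MASS, X = mean(.RESIDUE_MASS))[aa]
  if (anyNA(masses)) {
    stop("illegal amino-acid character(s): ",
         paste(unique(aa[is.na(masses)]), collapse = ", "))
  }
  sum(masses) + .WATER_MASS
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`.
#' @return The reverse complement (N maps to N).
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

# Scan one strand's three frames; s is the working-strand sequence.
# Returns rows with 0-based half-open [start, end) on the working strand.
.scan_frames <- function(s, code, require_atg, min_aa) {
  L <- nchar(s)
  out <- list()
  for (f in 0:2) {
    n_codon <- (L - f) %/% 3L
    if (n_codon < 1L) next
    starts <- f + 3L * (seq_len(n_codon) - 1L)          # 0-based codon starts
    codons <- substring(s, starts + 1L, starts + 3L)
    aas <- unname(code[codons])                          # NA for N codons
    open <- FALSE
    orf_first_codon <- NA_integer_
    atg_codon <- NA_integer_    # first ATG inside a 5'-truncated leading ORF
    complete5 <- FALSE
    frame_leading <- TRUE
    seg_start_codon <- 1L   # first codon of the current inter-stop segment
    # close the open ORF; last_codon = last translated codon; when
    # complete3, the span additionally covers the stop codon at last_codon+1
    close_orf <- function(last_codon, complete3) {
      if (last_codon < orf_first_codon) return(invisible())
      end0 <- starts[last_codon] + 3L + (if (complete3) 3L else 0L)
      emit <- function(first_codon, c5) {
        protein <- paste(aas[first_codon:last_codon], collapse = "")
        if (nchar(protein) >= min_aa) {
          out[[length(out) + 1L]] <<- list(
            frame = f, start = starts[first_codon], end = end0,
            protein = protein, complete5 = c5, complete3 = complete3)
        }
      }
      emit(orf_first_codon, complete5)
      # a 5'-truncated leading ORF may contain the genuine initiator: report
      # the ATG-initiated reading as well
      if (!complete5 && require_atg && !is.na(atg_codon) &&
          atg_codon <= last_codon) {
        emit(atg_codon, TRUE)
      }
    }
    for (j in seq_len(n_codon)) {
      a <- aas[j]
      if (is.na(a) || a == "*") {         # stop, or N codon (never translates)
        if (open) {
          close_orf(j - 1L, complete3 = !is.na(a))
          open <- FALSE
        }
        frame_leading <- FALSE
        seg_start_codon <- j + 1L
        atg_codon <- NA_integer_
      } else {
        if (!open) {
          if (codons[j] == "ATG") {
            open <- TRUE; complete5 <- TRUE
            orf_first_codon <- j
          } else if (!require_atg || (frame_leading && j == seg_start_codon)) {
            # frame-leading segment: the true start may lie off-contig
            open <- TRUE; complete5 <- FALSE
            orf_first_codon <- j
          }
        } else if (!complete5 && is.na(atg_codon) && codons[j] == "ATG") {
          atg_codon <- j
        }
      }
    }
    if (open) {                            # truncated by the contig end
      close_orf(n_codon, complete3 = FALSE)
    }
  }
  out
}

#' Find open reading frames in all six frames of a contig
#'
#' An ORF runs from its initiator to the next in-frame stop codon. With
#' `require_atg = TRUE` the initiator is the first ATG of an inter-stop
#' segment; the segment leading each frame (before any stop) is additionally
#' reported from the contig terminus with `complete5 = FALSE`, because
#' assemblies truncate 5' ends. With `require_atg = FALSE` an ORF opens at
#' the first codon after a stop (or the frame start). ORFs running off the
#' contig end get `complete3 = FALSE`. Codons containing `N` never translate:
#' they terminate the current ORF (without a stop) and scanning resumes
#' after them.
#'
#' Coordinates are 0-based half-open on the plus strand; when `complete3` is
#' `TRUE` the span includes the stop codon, so `(end - start)` is divisible
#' by 3 for complete ORFs and the protein has `(end - start)/3 - 1` residues.
#'
#' @param contig A list or one-row data.frame with elements `id` and `seq`.
#' @param genetic_code_id NCBI genetic code id (default 1, standard code).
#' @param require_atg Require an ATG initiator inside the contig
#'   (terminal-truncated ORFs are still reported; see Details).
#' @param min_aa Minimum protein length (residues) to report.
#' @return A data.frame with columns `contig_id`, `strand` (`"+"`/`"-"`),
#'   `frame` (0–2 on the reported strand), `start`, `end` (0-based half-open,
#'   plus-strand coordinates), `protein`, `mass_da`, `complete5`,
#'   `complete3`, sorted by protein length descending.
#' @export
find_orfs <- function(contig, genetic_code_id = 1L, require_atg = TRUE,
                      min_aa = 30L) {
  if (is.data.frame(contig)) contig <- as.list(contig[1L, ])
  seq <- toupper(contig$seq)
  if (!nzchar(seq)) stop("contig sequence is empty")
  code <- tryCatch(
    Biostrings::getGeneticCode(as.character(genetic_code_id)),
    error = function(e) stop("unknown genetic_code_id: ", genetic_code_id))
  L <- nchar(seq)
  plus <- .scan_frames(seq, code, require_atg, min_aa)
  minus <- .scan_frames(revcomp(seq), code, require_atg, min_aa)
  rows <- c(
    lapply(plus, function(o) {
      data.frame(contig_id = contig$id, strand = "+", frame = o$frame,
                 start = o$start, end = o$end, protein = o$protein,
                 complete5 = o$complete5, complete3 = o$complete3,
                 stringsAsFactors = FALSE)
    }),
    lapply(minus, function(o) {
      # mirror working-strand coordinates back onto the plus strand
      data.frame(contig_id = contig$id, strand = "-", frame = o$frame,
                 start = L - o$end, end = L - o$start, protein = o$protein,
                 complete5 = o$complete5, complete3 = o$complete3,
                 stringsAsFactors = FALSE)
    }))
  if (length(rows) == 0L) {
    return(data.frame(contig_id = character(0), strand = character(0),
                      frame = integer(0), start = integer(0), end = integer(0),
                      protein = character(0), mass_da = numeric(0),
                      complete5 = logical(0), complete3 = logical(0)))
  }
  df <- do.call(rbind, rows)
  df$mass_da <- vapply(df$protein, protein_mass, numeric(1), USE.NAMES = FALSE)
  df <- df[order(-nchar(df$protein)), c("contig_id", "strand", "frame",
                                        "start", "end", "protein", "mass_da",
                                        "complete5", "complete3")]
  rownames(df) <- NULL
  df
}

#' Select ORFan candidate contigs
#'
#' Stage-1 filter of the discovery pipeline. A contig is a candidate iff it
#' has no database hit, is strictly longer than `min_len` nucleotides, and
#' encodes at least one ORF whose protein is strictly heavier than
#' `min_mass` Daltons ("longer than 1,000 bp", "more than 15 kDa"). The
#' heaviest qualifying ORF is retained as `best_orf`. Filters are applied in
#' order (hit, length, mass) and the first failing filter is recorded as the
#' rejection reason.
#'
#' @param contigs data.frame from [read_fasta()].
#' @param hit_queries Character vector of contig ids having a database hit
#'   (from [read_hits_table()]).
#' @param min_len Minimum contig length, exclusive (nt; default 1000).
#' @param min_mass Minimum best-ORF protein mass, exclusive (Da; default
#'   15000).
#' @param genetic_code_id,require_atg,min_aa Passed to [find_orfs()].
#' @return A data.frame with one row per input contig: `contig_id`, `length`,
#'   `accepted`, `reason` (`""` when accepted), and for accepted contigs the
#'   best ORF's `orf_strand`, `orf_start1`/`orf_end1` (1-based inclusive),
#'   `protein`, `protein_len`, `mass_da`.
#' @export
select_orfan_candidates <- function(contigs, hit_queries,
                                    min_len = 1000L, min_mass = 15000,
                                    genetic_code_id = 1L, require_atg = TRUE,
                                    min_aa = 30L) {
  n <- nrow(contigs)
  res <- data.frame(
    contig_id = contigs$id, length = contigs$length,
    accepted = logical(n), reason = character(n),
    orf_strand = rep(NA_character_, n), orf_start1 = rep(NA_integer_, n),
    orf_end1 = rep(NA_integer_, n), protein = rep(NA_character_, n),
    protein_len = rep(NA_integer_, n), mass_da = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (contigs$id[i] %in% hit_queries) {
      res$reason[i] <- "database hit"
      next
    }
    if (contigs$length[i] <= min_len) {
      res$reason[i] <- "length"
      next
    }
    orfs <- find_orfs(list(id = contigs$id[i], seq = contigs$seq[i]),
                      genetic_code_id = genetic_code_id,
                      require_atg = require_atg, min_aa = min_aa)
    heavy <- orfs[orfs$mass_da > min_mass, , drop = FALSE]
    if (nrow(heavy) == 0L) {
      res$reason[i] <- "protein mass"
      next
    }
    best <- heavy[which.max(heavy$mass_da), ]
    res$accepted[i] <- TRUE
    res$orf_strand[i] <- best$strand
    res$orf_start1[i] <- best$start + 1L   # 1-based inclusive for reports
    res$orf_end1[i] <- best$end
    res$protein[i] <- best$protein
    res$protein_len[i] <- nchar(best$protein)
    res$mass_da[i] <- best$mass_da
  }
  res
}
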