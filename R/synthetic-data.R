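# Run expr with the global RNG seeded, restoring any pre-existing RNG state.
# All generator randomness flows from one integer seed.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.AA20 <- names(.RESIDUE_MASS)

# random synonymous back-translation of a protein (standard code)
.backtranslate <- function(protein) {
  code <- Biostrings::getGeneticCode("1")
  by_aa <- split(names(code), unname(code))
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(x) {
    cods <- by_aa[[x]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# planted protein positions (1-based), fixed offsets so that equal-offset
# proteins align column-wise: motif-A D, motif-B GG, motif-C triad center
.MOTIF_LAYOUT <- list(posA_D = 40L, posB = c(70L, 71L), posC = 85L)

#' Generate an RdRP-like contig with planted palm-domain motifs
#'
#' Builds a contig carrying a single long ATG-initiated, stop-terminated ORF
#' whose translation weighs more than 15 kDa and contains, in order, a
#' D-centred motif-A word, a GG motif-B word, and the requested motif-C
#' triad, at fixed recorded protein positions. Flanking UTRs are random.
#' Identical `(length, triad, seed)` yield byte-identical contigs.
#'
#' @param length Contig length in nt (at least 1200, so the mass constraint
#'   is satisfiable).
#' @param triad 3-residue motif-C triad to plant; the central residue must
#'   be `D` (the catalytic aspartate).
#' @param seed Integer seed.
#' @param id Contig id.
#' @return A list with `contig` (list `id`, `seq`, `length`) and `truth`:
#'   planted ORF coordinates (0-based half-open, plus strand), protein,
#'   motif positions (1-based protein coordinates) and triad.
#' @export
make_rdrp_contig <- function(length, triad, seed, id = "rdrp1") {
  if (length < 1200L) {
    stop("length too short to satisfy the 15 kDa mass constraint: ", length)
  }
  if (nchar(triad) != 3L || !all(strsplit(triad, "")[[1L]] %in% .AA20)) {
    stop("triad must be 3 standard amino-acid letters")
  }
  .with_seed(seed, {
    utr5 <- 30L
    utr3_min <- 25L
    n_aa <- (length - utr5 - utr3_min - 6L) %/% 3L   # residues excl. M? incl M
    lay <- .MOTIF_LAYOUT
    if (n_aa < lay$posC + 2L) stop("length too short for the motif layout")
    prot <- c("M", sample(.AA20, n_aa - 1L, replace = TRUE))
    prot[lay$posA_D - 1L] <- "F"                      # motif-A word F-D-S
    prot[lay$posA_D] <- "D"
    prot[lay$posA_D + 1L] <- "S"
    prot[lay$posB] <- "G"
    prot[(lay$posC - 1L):(lay$posC + 1L)] <- strsplit(triad, "")[[1L]]
    protein <- paste(prot, collapse = "")
    orf_nt <- .backtranslate(protein)
    utr3 <- length - utr5 - nchar(orf_nt) - 3L
    # in-frame stop at the 5'UTR end so the planted ATG is the initiator
    seq <- paste0(.random_nt(utr5 - 3L), "TAA", orf_nt, "TAA",
                  .random_nt(utr3))
    stopifnot(nchar(seq) == length)
    mass <- protein_mass(protein)
    if (mass <= 15000) stop("planted ORF below the 15 kDa constraint")
    list(contig = list(id = id, seq = seq, length = length),
         truth = list(orf_start = utr5, orf_end = utr5 + nchar(orf_nt) + 3L,
                      strand = "+", protein = protein, mass_da = mass,
                      motif = c(lay, list(triad = triad))))
  })
}

# companion (RNA2-like) contig: a plain long-ORF contig whose first and last
# `terminal_k` nt are overwritten with the partner's termini
.make_companion_contig <- function(rna1_seq, length, terminal_k, seed, id) {
  .with_seed(seed, {
    utr5 <- 30L
    utr3_min <- 25L
    n_aa <- (length - utr5 - utr3_min - 6L) %/% 3L
    prot <- c("M", sample(.AA20, n_aa - 1L, replace = TRUE))
    protein <- paste(prot, collapse = "")
    orf_nt <- .backtranslate(protein)
    utr3 <- length - utr5 - nchar(orf_nt) - 3L
    seq <- paste0(.random_nt(utr5 - 3L), "TAA", orf_nt, "TAA",
                  .random_nt(utr3))
    substr(seq, 1L, terminal_k) <- substr(rna1_seq, 1L, terminal_k)
    substr(seq, length - terminal_k + 1L, length) <-
      substr(rna1_seq, nchar(rna1_seq) - terminal_k + 1L, nchar(rna1_seq))
    list(contig = list(id = id, seq = seq, length = length),
         truth = list(orf_start = utr5, orf_end = utr5 + nchar(orf_nt) + 3L,
                      strand = "+", protein = protein,
                      mass_da = protein_mass(protein)))
  })
}

.mutate_read <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(chars)) < error_rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
  }
  paste(chars, collapse = "")
}

#' Simulate stranded reads from one contig as SAM records
#'
#' The number of reads is Poisson(`depth`); each read's RNA of origin is
#' plus-sense with probability `plus_fraction`. FLAG and sequence are set so
#' that [tally_strand()] under the same protocol decodes the origin exactly:
#' under `fr_firststrand` a plus-origin read aligns in reverse (flag 16) and
#' carries the reverse complement of its contig window. Substitution errors
#' are applied per base at `error_rate`.
#'
#' @param contig List with `id`, `seq` (and `length`).
#' @param depth Mean read count.
#' @param plus_fraction Probability a read originates from plus-sense RNA.
#' @param protocol `"fr_firststrand"` or `"fr_secondstrand"`.
#' @param error_rate Per-base substitution probability.
#' @param read_len Read length in nt (contig must be at least this long).
#' @param seed Integer seed.
#' @param paired Emit read pairs (R1/R2 with opposite orientations) instead
#'   of single-end reads.
#' @return Character vector of SAM body lines, with attributes `n_plus` and
#'   `n_minus` recording the true origin tallies.
#' @export
simulate_stranded_reads <- function(contig, depth, plus_fraction,
                                    protocol = c("fr_firststrand",
                                                 "fr_secondstrand"),
                                    error_rate = 0, read_len = 150L,
                                    seed = 1L, paired = FALSE) {
  protocol <- match.arg(protocol)
  L <- nchar(contig$seq)
  if (L < read_len) stop("contig shorter than read_len")
  .with_seed(seed, {
    n <- stats::rpois(1L, depth)
    if (n == 0L) {
      out <- character(0)
      attr(out, "n_plus") <- 0L
      attr(out, "n_minus") <- 0L
      out
    } else {
    pos <- sample.int(L - read_len + 1L, n, replace = TRUE)
    origin_plus <- stats::runif(n) < plus_fraction
    # forward-aligned R1 = minus origin under fr_firststrand
    r1_reverse <- if (protocol == "fr_firststrand") origin_plus else !origin_plus
    lines <- character(0)
    for (i in seq_len(n)) {
      window <- substr(contig$seq, pos[i], pos[i] + read_len - 1L)
      qname <- sprintf("%s_read%04d", contig$id, i)
      if (!paired) {
        flag <- if (r1_reverse[i]) 16L else 0L
        seq_out <- if (r1_reverse[i]) revcomp(window) else window
        lines <- c(lines, paste(qname, flag, contig$id, pos[i], 60L,
                                paste0(read_len, "M"), "*", 0L, 0L,
                                .mutate_read(seq_out, error_rate), "*",
                                sep = "\t"))
      } else {
        f1 <- bitwOr(bitwOr(0x1, 0x40), if (r1_reverse[i]) 0x10 else 0L)
        f2 <- bitwOr(bitwOr(0x1, 0x80), if (!r1_reverse[i]) 0x10 else 0L)
        s1 <- if (r1_reverse[i]) revcomp(window) else window
        s2 <- if (!r1_reverse[i]) revcomp(window) else window
        lines <- c(lines,
                   paste(qname, f1, contig$id, pos[i], 60L,
                         paste0(read_len, "M"), "=", pos[i], 0L,
                         .mutate_read(s1, error_rate), "*", sep = "\t"),
                   paste(qname, f2, contig$id, pos[i], 60L,
                         paste0(read_len, "M"), "=", pos[i], 0L,
                         .mutate_read(s2, error_rate), "*", sep = "\t"))
      }
    }
    attr(lines, "n_plus") <- sum(origin_plus)
    attr(lines, "n_minus") <- sum(!origin_plus)
    lines
    }
  })
}

#' Generate a synthetic RdRP protein alignment with planted motifs
#'
#' Rows are random proteins sharing conserved anchor columns: `D` at `colA`,
#' `G` at both `colB` columns and the planted triad at
#' `(colC - 1, colC, colC + 1)`. Noise corrupts each motif-A/motif-B anchor
#' column in exactly `floor(noise * n_seqs)` rows (sampled), so the realized
#' conservation is at least `1 - noise` and the conservation-threshold
#' behaviour is exact; the triad cells are the planted payload and stay
#' intact.
#'
#' @param n_seqs Number of rows.
#' @param n_col Alignment width.
#' @param triads Character vector of triads, recycled over rows; central
#'   residue must be `D`.
#' @param colA,colB,colC Anchor columns (`colB` length 2).
#' @param noise Per-cell corruption probability for the A/B anchor columns.
#' @param seed Integer seed.
#' @return Named character vector of aligned rows, with attribute `truth`
#'   (anchors and per-row triads).
#' @export
make_rdrp_msa <- function(n_seqs = 10L, n_col = 120L, triads = "NDD",
                          colA = 20L, colB = c(50L, 51L), colC = 80L,
                          noise = 0, seed = 1L) {
  stopifnot(colA < colB[1L], colB[2L] < colC - 1L, colC + 1L <= n_col)
  triads <- rep_len(triads, n_seqs)
  if (any(substr(triads, 2L, 2L) != "D")) {
    stop("planted triads must carry the central catalytic D")
  }
  .with_seed(seed, {
    grid <- lapply(seq_len(n_seqs), function(i) {
      r <- sample(.AA20, n_col, replace = TRUE)
      r[colA] <- "D"
      r[colB] <- "G"
      r[(colC - 1L):(colC + 1L)] <- strsplit(triads[i], "")[[1L]]
      r
    })
    n_corrupt <- floor(noise * n_seqs)
    for (cc in c(colA, colB)) {
      for (i in sample.int(n_seqs, n_corrupt)) {
        grid[[i]][cc] <- sample(.AA20, 1L)
      }
    }
    rows <- vapply(grid, paste, character(1), collapse = "")
    names(rows) <- sprintf("virus%02d_RNA1", seq_len(n_seqs))
    attr(rows, "truth") <- list(colA = colA, colB = colB, colC = colC,
                                triads = stats::setNames(triads, names(rows)))
    rows
  })
}

#' Write a Table-2-shaped stranded count table
#'
#' Columns: segment id, `length`, then `<lib>`, `<lib>pos`, `<lib>neg`
#' triplets. Inverse of [read_strand_counts()] for comma-free integers.
#'
#' @param long data.frame with `segment_id`, `library_id`, `total`, `plus`,
#'   `minus` (and optionally `length` per segment).
#' @param path Output path.
#' @param lengths Optional named vector of segment lengths.
#' @return `path`, invisibly.
#' @export
write_strand_counts <- function(long, path, lengths = NULL) {
  segs <- unique(long$segment_id)
  libs <- unique(long$library_id)
  header <- c("Virus", "length",
              unlist(lapply(libs, function(l) c(l, paste0(l, "pos"),
                                                paste0(l, "neg")))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  for (s in segs) {
    row <- c(s, if (is.null(lengths)) "" else as.character(lengths[[s]]))
    for (l in libs) {
      hit <- long[long$segment_id == s & long$library_id == l, , drop = FALSE]
      if (nrow(hit) == 1L) {
        row <- c(row, hit$total, hit$plus, hit$minus)
      } else {
        row <- c(row, 0L, 0L, 0L)
      }
    }
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Default parameters for the synthetic input bundle
#'
#' The defaults emulate the structure of the study system: a handful of host
#' transcripts with database hits and sense-only (mRNA) reads, and a few
#' bisegmented viruses — an RdRP (RNA1) contig with planted A/B/C motifs
#' paired with a companion (RNA2) contig sharing 20-nt termini — carrying
#' reads on both strands, each virus present in a subset of samples.
#'
#' @param n_host Number of host contigs (hits + sense-only reads).
#' @param n_viruses Number of virus pairs (RNA1 + RNA2 each).
#' @param contig_len_range RNA1 length range (nt).
#' @param rna2_len_range RNA2 length range (nt).
#' @param read_len Read length (nt).
#' @param depth_per_contig Mean reads per contig per positive sample.
#' @param plus_fraction Per-virus plus-sense read fraction (recycled;
#'   default 0.7, plus-dominant replication).
#' @param host_plus_fraction Host contigs' plus fraction (default 1: pure
#'   mRNA; lower it to create hard negatives with antisense transcription).
#' @param substitution_error_rate Per-base read error rate.
#' @param triads Motif-C triads planted in RNA1 ORFs (recycled).
#' @param terminal_k Shared terminal length between segment pairs (nt).
#' @param n_samples Number of samples/libraries.
#' @param protocol Stranded library protocol for the emitted SAM.
#' @param seed Integer master seed; every other seed is derived from it.
#' @return Named list of parameters for [generate_dataset()].
#' @export
synthetic_params <- function(n_host = 5L, n_viruses = 3L,
                             contig_len_range = c(2000L, 3200L),
                             rna2_len_range = c(1400L, 1900L),
                             read_len = 150L, depth_per_contig = 200,
                             plus_fraction = 0.7, host_plus_fraction = 1.0,
                             substitution_error_rate = 0,
                             triads = c("NDD", "SDD", "GDQ"),
                             terminal_k = 20L, n_samples = 4L,
                             protocol = "fr_firststrand", seed = 1L) {
  as.list(environment())
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Emits every file the discovery pipeline consumes — contig FASTA, a
#' 12-column hits table listing every host contig (and no viral contig), one
#' SAM per sample, a Ct table consistent with per-sample presence
#' (Ct ~ Uniform(20, 30) when present, blank when absent), a Table-2-shaped
#' count table, a padded RdRP protein alignment with the planted motifs, and
#' a JSON truth manifest. Identical parameters and seed give a byte-identical
#' bundle.
#'
#' @param params List from [synthetic_params()].
#' @param out_dir Output directory (created if needed).
#' @return A list with `paths` (named file paths), `manifest` (the truth:
#'   contig labels, RNA1/RNA2 pairings, planted ORFs/motifs/triads, per-virus
#'   plus fraction, per-sample presence) and `contigs` (the contig
#'   data.frame).
#' @export
generate_dataset <- function(params = synthetic_params(), out_dir) {
  p <- params
  if (p$n_samples < 1L) stop("n_samples must be at least 1")
  if (p$n_viruses < 1L) stop("n_viruses must be at least 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plus_fraction <- rep_len(p$plus_fraction, p$n_viruses)
  triads <- rep_len(p$triads, p$n_viruses)
  samples <- sprintf("S%02d", seq_len(p$n_samples))

  contigs <- list()
  truth <- list()
  pairings <- list()
  if (p$n_viruses > 2^p$n_samples - 1L) {
    stop("n_viruses exceeds the number of distinct presence patterns ",
         "available with ", p$n_samples, " samples")
  }
  # each virus infects its own distinct, non-empty set of samples, so
  # presence patterns discriminate viruses (co-segregation)
  presence <- .with_seed(p$seed, {
    m <- matrix(FALSE, p$n_viruses, p$n_samples,
                dimnames = list(sprintf("virus%02d", seq_len(p$n_viruses)),
                                samples))
    seen <- character(0)
    for (v in seq_len(p$n_viruses)) {
      repeat {
        row <- logical(p$n_samples)
        row[sample.int(p$n_samples, sample.int(p$n_samples, 1L))] <- TRUE
        key <- paste(as.integer(row), collapse = "")
        if (!(key %in% seen)) break
      }
      seen <- c(seen, key)
      m[v, ] <- row
    }
    m
  })

  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    (p$seed * 7919L + si * 104729L) %% 2147483647L
  }

  for (v in seq_len(p$n_viruses)) {
    id1 <- sprintf("virus%02d_RNA1", v)
    id2 <- sprintf("virus%02d_RNA2", v)
    r1 <- make_rdrp_contig(
      .with_seed(p$seed + v,
                 sample(p$contig_len_range[1L]:p$contig_len_range[2L], 1L)),
      triads[v], seed = next_seed(), id = id1)
    r2 <- .make_companion_contig(r1$contig$seq,
                                 .with_seed(p$seed + 100L + v,
                                            sample(p$rna2_len_range[1L]:p$rna2_len_range[2L], 1L)),
                                 p$terminal_k, seed = next_seed(), id = id2)
    contigs[[id1]] <- r1$contig
    contigs[[id2]] <- r2$contig
    truth[[id1]] <- c(r1$truth, list(label = "viral_rna1"))
    truth[[id2]] <- c(r2$truth, list(label = "viral_rna2"))
    pairings[[length(pairings) + 1L]] <- list(rna1 = id1, rna2 = id2)
  }
  for (h in seq_len(p$n_host)) {
    id <- sprintf("host%02d", h)
    hc <- .with_seed(next_seed(), {
      len <- sample(1200:2500, 1L)
      list(id = id, seq = .random_nt(len), length = len)
    })
    contigs[[id]] <- hc
    truth[[id]] <- list(label = "host")
  }

  contig_df <- data.frame(
    id = vapply(contigs, `[[`, character(1), "id"),
    seq = vapply(contigs, `[[`, character(1), "seq"),
    length = vapply(contigs, function(x) nchar(x$seq), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  paths <- list(
    contigs = file.path(out_dir, "contigs.fasta"),
    hits = file.path(out_dir, "hits.tsv"),
    sam = stats::setNames(file.path(out_dir, paste0(samples, ".sam")), samples),
    ct = file.path(out_dir, "ct_table.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    msa = file.path(out_dir, "rdrp_msa.fasta"),
    manifest = file.path(out_dir, "manifest.json"))

  write_fasta(contig_df, paths$contigs)

  # hits table: every host contig, no viral contig
  hit_lines <- vapply(seq_len(p$n_host), function(h) {
    paste(sprintf("host%02d", h), sprintf("db_protein_%03d", h),
          "95.0", "400", "5", "0", "1", "400", "10", "409",
          "1e-50", "700", sep = "\t")
  }, character(1))
  writeLines(hit_lines, paths$hits)

  # stranded reads per sample
  viral_ids <- unlist(lapply(pairings, function(x) c(x$rna1, x$rna2)))
  long_counts <- list()
  for (s in seq_along(samples)) {
    body <- character(0)
    for (id in contig_df$id) {
      lab <- truth[[id]]$label
      if (lab == "host") {
        pf <- p$host_plus_fraction
        active <- TRUE
      } else {
        v <- as.integer(sub("virus(\\d+)_RNA[12]", "\\1", id))
        pf <- plus_fraction[v]
        active <- presence[v, s]
      }
      if (!active) next
      rl <- simulate_stranded_reads(contigs[[id]], p$depth_per_contig, pf,
                                    protocol = p$protocol,
                                    error_rate = p$substitution_error_rate,
                                    read_len = p$read_len,
                                    seed = next_seed())
      body <- c(body, rl)
      long_counts[[length(long_counts) + 1L]] <- data.frame(
        segment_id = id, library_id = samples[s],
        total = attr(rl, "n_plus") + attr(rl, "n_minus"),
        plus = attr(rl, "n_plus"), minus = attr(rl, "n_minus"),
        stringsAsFactors = FALSE)
    }
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                vapply(contig_df$id, function(id)
                  sprintf("@SQ\tSN:%s\tLN:%d", id,
                          nchar(contig_df$seq[contig_df$id == id])),
                  character(1), USE.NAMES = FALSE))
    writeLines(c(header, body), paths$sam[[s]])
  }
  long_df <- do.call(rbind, long_counts)
  # complete missing segment x library combinations with zeros
  full <- expand.grid(segment_id = contig_df$id, library_id = samples,
                      stringsAsFactors = FALSE)
  long_df <- merge(full, long_df, all.x = TRUE, sort = FALSE)
  long_df[is.na(long_df)] <- 0L
  long_df <- long_df[order(match(long_df$segment_id, contig_df$id),
                           match(long_df$library_id, samples)), ]
  write_strand_counts(long_df, paths$counts,
                      lengths = stats::setNames(contig_df$length,
                                                contig_df$id))

  # Ct table over viral segments
  ct <- matrix(NA_real_, length(viral_ids), p$n_samples,
               dimnames = list(viral_ids, samples))
  ct_vals <- .with_seed(next_seed(),
                        round(stats::runif(length(ct), 20, 30), 2))
  for (i in seq_along(viral_ids)) {
    v <- as.integer(sub("virus(\\d+)_RNA[12]", "\\1", viral_ids[i]))
    ct[i, presence[v, ]] <- ct_vals[(i - 1L) * p$n_samples +
                                      which(presence[v, ])]
  }
  write_ct_table(ct, paths$ct)

  # padded RdRP protein MSA (fixed motif offsets align column-wise)
  rna1_ids <- vapply(pairings, `[[`, character(1), "rna1")
  prots <- vapply(rna1_ids, function(id) truth[[id]]$protein, character(1))
  wid <- max(nchar(prots))
  msa <- stats::setNames(
    vapply(prots, function(x)
      paste0(x, strrep("-", wid - nchar(x))), character(1), USE.NAMES = FALSE),
    rna1_ids)
  write_fasta(msa, paths$msa)

  manifest <- list(
    labels = lapply(truth, `[[`, "label"),
    pairings = pairings,
    orfs = lapply(truth[viral_ids], function(t)
      list(start = t$orf_start, end = t$orf_end, strand = t$strand,
           protein_len = nchar(t$protein), mass_da = t$mass_da)),
    motifs = lapply(truth[rna1_ids], `[[`, "motif"),
    plus_fraction = stats::setNames(as.list(plus_fraction),
                                    sprintf("virus%02d", seq_len(p$n_viruses))),
    presence = lapply(seq_len(p$n_viruses), function(v)
      samples[presence[v, ]]),
    params = p[setdiff(names(p), character(0))])
  names(manifest$presence) <- sprintf("virus%02d", seq_len(p$n_viruses))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  list(paths = paths, manifest = manifest, contigs = contig_df,
       presence = presence)
}
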