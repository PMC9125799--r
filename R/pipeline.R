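#' Build a pipeline configuration
#'
#' Collects every tunable of the discovery pipeline in one place; all values
#' are echoed verbatim into the run's `summary.json`.
#'
#' @param contigs Path to the contig FASTA.
#' @param hits Path to the 12-column tabular hits file.
#' @param alignments Named character vector of SAM paths (names = library
#'   ids; unnamed paths are labelled by file name).
#' @param ct Optional path to a Ct table.
#' @param counts Optional path to a Table-2-shaped count table.
#' @param msa Optional path to an aligned protein FASTA of the candidate
#'   RdRPs (the motif stage needs an alignment and is recorded as not run
#'   without one).
#' @param out_dir Output directory.
#' @param evalue_max Hit e-value cutoff for the no-match filter.
#' @param min_len,min_mass Candidate filters (strict; nt and Da).
#' @param genetic_code_id,require_atg ORF-calling options.
#' @param protocol Stranded protocol of the libraries.
#' @param min_each,min_total,dominance_ratio Strand-profile options.
#' @param identity_threshold Clade clustering threshold (percent identity).
#' @param motif_min_frac Motif-anchor conservation threshold.
#' @param rules Association thresholds from [association_rules()].
#' @param ct_cutoff Ct presence cutoff.
#' @return A named list (class `orfanscan_config`).
#' @export
pipeline_config <- function(contigs, hits, alignments, ct = NULL,
                            counts = NULL, msa = NULL, out_dir,
                            evalue_max = 1e-3, min_len = 1000L,
                            min_mass = 15000, genetic_code_id = 1L,
                            require_atg = TRUE,
                            protocol = "fr_firststrand", min_each = 1L,
                            min_total = 10L, dominance_ratio = 1.0,
                            identity_threshold = 15.0,
                            motif_min_frac = 0.7,
                            rules = association_rules(),
                            ct_cutoff = 38.0) {
  cfg <- as.list(environment())
  if (is.null(names(cfg$alignments)) && length(cfg$alignments)) {
    names(cfg$alignments) <- tools::file_path_sans_ext(basename(cfg$alignments))
  }
  class(cfg) <- "orfanscan_config"
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the ORFan virus-discovery pipeline end to end
#'
#' Executes the five analysis stages in order: candidate selection (no
#' database hit, length, protein mass), strand profiling (both-strand filter
#' and polarity), clade clustering on pairwise protein identity, palm-domain
#' motif/triad extraction (when a protein alignment is supplied), and
#' RNA1–RNA2 segment association. Each stage writes a TSV into `out_dir`;
#' `summary.json` holds the headline numbers plus the full effective
#' configuration.
#'
#' @param config List from [pipeline_config()].
#' @return The summary as a list (invisibly also written to
#'   `out_dir/summary.json`).
#' @export
run_discovery <- function(config) {
  cfg <- config
  for (f in c(cfg$contigs, cfg$hits, cfg$alignments)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: ORFan candidate selection
  contigs <- read_fasta(cfg$contigs)
  hit_queries <- read_hits_table(cfg$hits, evalue_max = cfg$evalue_max)
  cand <- select_orfan_candidates(contigs, hit_queries,
                                  min_len = cfg$min_len,
                                  min_mass = cfg$min_mass,
                                  genetic_code_id = cfg$genetic_code_id,
                                  require_atg = cfg$require_atg)
  .write_tsv(cbind(cand[, setdiff(names(cand), "protein")],
                   mass_kda = round(cand$mass_da / 1000, 2)),
             file.path(cfg$out_dir, "candidates.tsv"))
  kept <- cand[cand$accepted, , drop = FALSE]

  # stage 2: strand profiling over all libraries
  profiles <- do.call(rbind, lapply(names(cfg$alignments), function(lib) {
    reads <- read_alignments(cfg$alignments[[lib]])
    tally_strand(reads, protocol = cfg$protocol, library_id = lib,
                 contig_ids = contigs$id)
  }))
  profiles <- classify_profile(profiles, min_each = cfg$min_each,
                               min_total = cfg$min_total,
                               dominance_ratio = cfg$dominance_ratio)
  .write_tsv(profiles, file.path(cfg$out_dir, "strand_profiles.tsv"))
  # a candidate survives if some library shows reads on both strands
  both_ok <- vapply(kept$contig_id, function(id)
    any(profiles$keep[profiles$contig_id == id]), logical(1))
  kept <- kept[both_ok, , drop = FALSE]

  # stage 3: clade clustering on candidate proteins
  clades <- NULL
  if (nrow(kept) >= 2L) {
    prots <- stats::setNames(kept$protein, kept$contig_id)
    idm <- pairwise_identity(prots, aligned = FALSE)
    write_identity_matrix(idm, file.path(cfg$out_dir, "identity_matrix.tsv"))
    clades <- cluster_clades(idm, threshold_pct = cfg$identity_threshold)
    .write_tsv(clades, file.path(cfg$out_dir, "clades.tsv"))
  }

  # stage 4: motif / triad extraction (needs a supplied protein alignment)
  motif_summary <- list(run = FALSE)
  if (!is.null(cfg$msa) && file.exists(cfg$msa)) {
    msa <- read_protein_fasta(cfg$msa)
    anchors <- locate_motif_anchors(msa, min_frac = cfg$motif_min_frac)
    if (isTRUE(anchors$found)) {
      tri <- extract_triads(msa, anchors)
      .write_tsv(tri$calls, file.path(cfg$out_dir, "triads.tsv"))
      writeLines(annotate_alignment(msa, anchors),
                 file.path(cfg$out_dir, "motif_alignment.txt"))
      motif_summary <- list(run = TRUE, anchors = anchors[c("colA", "colB",
                                                            "colC")],
                            tally = as.list(tri$tally), mode = tri$mode)
    } else {
      motif_summary <- list(run = TRUE, anchors = NULL, tally = list(),
                            mode = NA)
    }
  }

  # stage 5: segment association among surviving candidates
  assoc <- NULL
  if (nrow(kept) >= 2L) {
    seqs <- stats::setNames(contigs$seq, contigs$id)[kept$contig_id]
    presence <- NULL
    if (!is.null(cfg$ct) && file.exists(cfg$ct)) {
      presence <- binarize_ct(read_ct_table(cfg$ct), cutoff = cfg$ct_cutoff)
    }
    counts <- NULL
    if (!is.null(cfg$counts) && file.exists(cfg$counts)) {
      long <- read_strand_counts(cfg$counts)
      counts <- stats::xtabs(total ~ segment_id + library_id, data = long)
      counts <- matrix(counts, nrow(counts), ncol(counts),
                       dimnames = dimnames(counts))
    }
    # RdRP-bearing candidates (heaviest proteins) vs the rest: without
    # external annotation every candidate is tried in both roles
    assoc <- associate_segments(kept$contig_id, kept$contig_id, seqs = seqs,
                                presence = presence, counts = counts,
                                rules = cfg$rules)
    assoc <- assoc[assoc$rna1_id != assoc$rna2_id, , drop = FALSE]
    .write_tsv(assoc, file.path(cfg$out_dir, "associations.tsv"))
  }

  summary <- list(
    n_contigs = nrow(contigs),
    n_candidates = nrow(kept),
    candidates = kept$contig_id,
    n_clades = if (is.null(clades)) 0L else length(unique(clades$clade)),
    motifs = motif_summary,
    n_associated_pairs = if (is.null(assoc)) 0L
                         else sum(assoc$call == "associated") %/% 2L,
    associated_pairs = if (is.null(assoc)) list() else {
      ap <- assoc[assoc$call == "associated", c("rna1_id", "rna2_id")]
      ap <- ap[ap$rna1_id < ap$rna2_id, , drop = FALSE]   # dedupe symmetric
      unname(apply(ap, 1L, as.list))
    },
    config = .config_for_json(cfg))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(summary)
}

.config_for_json <- function(cfg) {
  out <- unclass(cfg)
  out$alignments <- as.list(out$alignments)
  out$out_dir <- NULL    # reports stay byte-identical across output locations
  out
}
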