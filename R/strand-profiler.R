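#' Tally plus/minus-origin reads per contig from stranded alignments
#'
#' Converts alignment orientation into RNA-of-origin strand under the stated
#' library protocol. Under `fr_firststrand` (the dUTP / TruSeq-stranded
#' convention) a single-end or first-in-pair read that aligns forward on the
#' contig was sequenced from the first cDNA strand, i.e. from RNA antisense
#' to the contig: it increments `minus`. A reverse alignment increments
#' `plus`. Second-in-pair reads follow the opposite rule, and
#' `fr_secondstrand` inverts all of it. Unmapped reads are ignored
#' (secondary/supplementary records were already dropped on read).
#'
#' @param reads data.frame from [read_alignments()].
#' @param protocol `"fr_firststrand"` (default) or `"fr_secondstrand"`.
#'   Misconfiguration silently inverts the biology, hence no auto-detection.
#' @param library_id Label recorded in the output (one SAM file = one
#'   library).
#' @param contig_ids Optional character vector of known contig ids; reads
#'   aligned to other references are counted separately with a warning, and
#'   contigs with no reads get a zero row.
#' @return A data.frame with one row per contig: `contig_id`, `library_id`,
#'   `plus`, `minus`, `total`.
#' @export
tally_strand <- function(reads, protocol = c("fr_firststrand",
                                             "fr_secondstrand"),
                         library_id = "lib1", contig_ids = NULL) {
  protocol <- match.arg(protocol)
  mapped <- reads[reads$is_mapped, , drop = FALSE]
  if (!is.null(contig_ids)) {
    unknown <- !(mapped$ref_id %in% contig_ids)
    if (any(unknown)) {
      warning(sum(unknown), " read(s) aligned to reference(s) outside the ",
              "contig set; excluded from tallies")
      mapped <- mapped[!unknown, , drop = FALSE]
    }
  }
  # origin strand: under fr_firststrand a forward-aligned single-end /
  # first-in-pair read derives from minus-sense RNA
  first_rule <- is.na(mapped$is_first_in_pair) | mapped$is_first_in_pair
  origin_plus <- ifelse(first_rule, mapped$is_reverse, !mapped$is_reverse)
  if (protocol == "fr_secondstrand") {
    origin_plus <- !origin_plus
  }
  ids <- if (is.null(contig_ids)) sort(unique(mapped$ref_id)) else contig_ids
  plus <- vapply(ids, function(id)
    sum(origin_plus[mapped$ref_id == id]), numeric(1))
  minus <- vapply(ids, function(id)
    sum(!origin_plus[mapped$ref_id == id]), numeric(1))
  data.frame(contig_id = ids, library_id = rep(library_id, length(ids)),
             plus = as.integer(plus), minus = as.integer(minus),
             total = as.integer(plus + minus),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify strand polarity and apply the both-strand replication filter
#'
#' A replicating RNA virus leaves reads on both strands of its genome
#' segment; contigs with reads on only one strand are discarded
#' (`keep = FALSE` when either strand count is below `min_each`). Polarity is
#' `minus_dominant` when `minus > dominance_ratio * plus`, `plus_dominant`
#' when `plus > dominance_ratio * minus`, otherwise `balanced`; profiles with
#' fewer than `min_total` reads are called `insufficient`.
#'
#' @param profiles data.frame from [tally_strand()] (or any data.frame with
#'   `plus` and `minus` columns).
#' @param min_each Minimum reads required on each strand to keep the contig
#'   (default 1: the literal one-strand-only discard rule).
#' @param min_total Minimum total reads for a polarity call (default 10).
#' @param dominance_ratio Fold-excess required to call dominance (default 1:
#'   any excess).
#' @return The input with `polarity` and `keep` columns added.
#' @export
classify_profile <- function(profiles, min_each = 1L, min_total = 10L,
                             dominance_ratio = 1.0) {
  plus <- profiles$plus
  minus <- profiles$minus
  total <- plus + minus
  polarity <- ifelse(total < min_total, "insufficient",
              ifelse(minus > dominance_ratio * plus, "minus_dominant",
              ifelse(plus > dominance_ratio * minus, "plus_dominant",
                     "balanced")))
  profiles$total <- total
  profiles$polarity <- polarity
  profiles$keep <- plus >= min_each & minus >= min_each
  profiles
}
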