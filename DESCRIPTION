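Package: orfanscan
Title: Discovery of ORFan RNA Virus Segments from Stranded Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying candidate RNA virus genome segments
    among assembled contigs that lack any database similarity ("ORFans").
    Candidates are selected by absence of protein-level database hits,
    nucleotide length, and encoded-protein molecular mass; stranded read
    alignments provide the replication hallmark (reads mapping to both
    strands) and a polarity classification; pairwise protein identity and
    single-linkage clustering group candidates into clades; palm-domain
    motifs A/B/C and the motif-C catalytic triad are located in protein
    alignments of putative RNA-dependent RNA polymerases; and RdRP (RNA1)
    segments are associated with companion (RNA2) segments through terminal
    sequence conservation, presence/absence co-occurrence across isolates at
    a qPCR Ct cutoff, and cross-library read-abundance correlation. A seeded
    synthetic-data generator emulates the full input bundle with a ground
    truth manifest so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pheatmap
Config/testthat/edition: 3
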