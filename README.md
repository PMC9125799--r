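# orfanscan

Discovery of ORFan RNA virus segments from stranded metatranscriptomes.

## The problem

Most RNA viruses are found by similarity search against annotated virus
databases. That approach is blind to *ORFans* — protein-coding sequences
with no detectable similarity to anything annotated — and a growing share of
the RNA virosphere, especially among fungal and oomycete viruses, lives
exactly there. `orfanscan` implements a discovery pipeline that works
*without* database similarity, using three independent signals that a
contig is a replicating RNA virus genome segment:

1. **Absence of evidence of a cellular origin.** A candidate has no
   protein-level database hit (e-value ≤ `evalue_max`), is longer than
   1,000 bp, and encodes an ORF heavier than 15 kDa — the typical size
   floor for a conserved protein on a mycovirus genome segment.
2. **Two-strand read support.** In a stranded RNA-seq library
   (dUTP / TruSeq protocol) each read's RNA of origin is known. A
   replicating RNA virus produces both genomic (+) and antigenomic (−)
   RNA, so reads must map to both strands of the contig; contigs with
   single-strand support only are discarded. The ratio also classifies
   each segment as plus- or minus-dominant — some clades accumulate mostly
   minus-sense RNA during infection.
3. **Behaving like a genome.** An RdRP-encoding segment (RNA1) is linked
   to a companion segment (RNA2) by three evidence streams: near-identical
   5'/3' termini (mismatches over the terminal *k* nt, no alignment),
   presence/absence co-segregation across isolates from qPCR Ct values
   (positive iff Ct ≤ 38; Jaccard and exact-set tests), and Pearson
   correlation of log10(reads + 1) across sequencing libraries.

Candidates are grouped into clades by single-linkage clustering of the
pairwise percent-identity matrix of their proteins (identity = matches /
columns where both sequences carry a residue), and the RdRP palm-domain
motifs are located in a protein alignment by conservation: a conserved
aspartate (motif A), a conserved glycine pair (motif B), and the catalytic
motif C, whose three central residues form the *catalytic triad* —
canonically GDD, with SDD/GDN as classical rarities and triads such as
NDD, ADD, HDD and GDQ marking deeply divergent RdRPs.

A fully seeded synthetic-data generator (`generate_dataset()`) emits the
complete input bundle — contigs, hits table, per-sample SAM, Ct table,
count table, RdRP alignment — together with a ground-truth manifest, so
every stage of the pipeline is testable without downloading anything.

## Worked example

The package ships the study's printed per-library stranded read counts and
the yeast qPCR panel as plain-text tables. Classifying the powdery-mildew
(PM-A) library profiles:

```r
library(orfanscan)
counts <- read_strand_counts(system.file("extdata", "study_read_counts.tsv",
                                         package = "orfanscan"))
pma <- counts[counts$library_id == "PMA" & counts$total > 0, ]
classify_profile(pma)
#>     segment_id library_id total plus minus       polarity keep
#>   ElaOMV1 RNA1        PMA  4810 3360  1450  plus_dominant TRUE
#>   ElaOMV1 RNA2        PMA  2072 1814   258  plus_dominant TRUE
#>   ElaOMV2 RNA1        PMA  3780  518  3262 minus_dominant TRUE
#>   ElaOMV2 RNA2        PMA  2898  462  2436 minus_dominant TRUE
#>  PvlaOMV3 RNA1        PMA   840  184   656 minus_dominant TRUE
#>  PvlaOMV3 RNA2        PMA  1060  210   850 minus_dominant TRUE
```

Every segment has reads on both strands (`keep`), and both segments of
ElaOMV2 are minus-dominant — the clade-level replication signature.
Segment association on the yeast panel and the cross-library counts:

```r
ct <- read_ct_table(system.file("extdata", "study_yeast_ct.tsv",
                                package = "orfanscan"))
pres <- binarize_ct(ct, cutoff = 38)
cooccurrence_score(pres["SbOMV1 RNA1", ], pres["SbOMV1 RNA2", ])
#> $jaccard [1] 1      $exact [1] TRUE      $n_shared_positive [1] 3

r1 <- counts[counts$segment_id == "PvlaOMV3 RNA1", ]
r2 <- counts[counts$segment_id == "PvlaOMV3 RNA2", ]
libs <- c("DMGA", "DMGE", "DMGD", "PMA", "PMGA")
abundance_correlation(r1$total[match(libs, r1$library_id)],
                      r2$total[match(libs, r2$library_id)])
#> $r [1] 0.9808941    $n_libraries_used [1] 5
```

The two SbOMV1 segments co-segregate perfectly across the 12 yeast
isolates (Jaccard 1, three shared positives), and the PvlaOMV3 segments'
abundances correlate at r = 0.98 across five libraries — two of the three
evidence streams that `call_association()` combines into an
associated/unresolved verdict.

An end-to-end run over a directory of inputs is one call
(`run_discovery(pipeline_config(...))`) or one shell command
(`Rscript inst/scripts/orfanscan.R run --contigs ... --hits ...
--alignments ... --out DIR`); `summary.json` in the output directory
carries candidate counts, clades, triad tallies, association calls and the
full effective configuration.

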