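---
title: "Discovering ORFan RNA virus segments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering ORFan RNA virus segments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfanscan)
```

## The discovery model

`orfanscan` identifies candidate RNA virus genome segments among assembled
contigs using signals that do not depend on sequence similarity to known
viruses. The underlying biological model is:

* A contig of *cellular* origin leaves two traces: a protein-level database
  hit, and — in a stranded RNA-seq library — reads from the sense strand
  only, because cellular transcripts are single-stranded mRNA.
* A contig that is a *replicating RNA virus segment* leaves neither: its
  protein is too diverged to hit the database, but replication through a
  complementary intermediate deposits reads on **both** strands.
* A *bisegmented* virus additionally couples its two segments: they carry
  near-identical 5' and 3' termini (recognized by the same polymerase),
  they infect the same host individuals, and their read abundances rise
  and fall together across sequencing libraries.

Each of these statements becomes a pipeline stage with an explicit,
configurable decision rule.

## Stage rules and parameters

### Candidate filter (`select_orfan_candidates`)

A contig is a candidate iff it has **no** hit at `evalue_max` (default
`1e-3`), its length is **strictly greater** than `min_len = 1000` nt, and
some ORF's protein is **strictly heavier** than `min_mass = 15000` Da.
Both inequalities are strict because the underlying rules are phrased as
"longer than" and "more than"; the boundary cases (exactly 1,000 nt,
exactly 15 kDa) are rejected and the rejection reason is recorded.

The no-hit e-value cutoff is not prescribed anywhere authoritative, so it
is an explicit parameter; `1e-3` is the permissive end of common DIAMOND
practice — permissive here is *conservative*, since any plausible hit
disqualifies a contig from being an ORFan.

ORF calling scans all six frames. With `require_atg = TRUE` (default) an
ORF runs from the first ATG of an inter-stop segment to the next in-frame
stop; the segment leading each frame is *additionally* reported from the
contig terminus with `complete5 = FALSE`, because assemblies routinely
truncate 5' ends and a mass filter must not discard a real protein for a
missing start codon. Codons containing `N` never translate: they terminate
the running ORF without a stop. Protein mass uses **average** (not
monoisotopic) residue masses plus one water, the convention of common
molecular-weight calculators; `X` contributes the unweighted mean of the
20 residue masses. The genetic code defaults to the standard code (id 1)
and is configurable for, e.g., mitochondrially-resident viruses.

### Strand profiling (`tally_strand`, `classify_profile`)

Under the dUTP/TruSeq convention (`fr_firststrand`) a single-end or
first-in-pair read aligning *forward* on the contig derives from RNA
*antisense* to it; `fr_secondstrand` inverts the rule, and second-in-pair
mates always contribute with the opposite rule of their mate. The protocol
is a mandatory configuration item rather than something sniffed from data,
because misconfiguration silently swaps the biology (a plus-dominant virus
becomes minus-dominant). Only primary alignments are counted, once each.

`keep` requires at least `min_each = 1` read on each strand — the literal
both-strands rule. Two additions make polarity calls robust on shallow
contigs: profiles with fewer than `min_total = 10` reads are called
`insufficient`, and dominance requires a `dominance_ratio`-fold excess
(default 1, i.e. any excess). Both are configurable and echoed in reports.

### Clade clustering (`pairwise_identity`, `cluster_clades`)

Percent identity between two aligned sequences is
`100 × matches / columns where both carry a residue`. The denominator
choice matters for gappy alignments of highly divergent proteins; the
both-non-gap rule is stated, tested, and deliberately *not* silently
comparable with tools that divide by alignment length or by the shorter
sequence. Pairs with no co-occupied columns score 0 with a warning.

Clades are connected components of the graph with an edge wherever
identity ≥ `threshold_pct` (single linkage). The default 15 % sits between
typical inter-clade (< 10 %) and intra-clade identities of highly
divergent RdRP groups. Labels `clade_1…clade_k` are deterministic:
descending size, ties broken by the lexicographically smallest member.
When no external alignment is given, pairs are aligned with an end-to-end
affine-gap aligner (BLOSUM62, gap open 11, extend 1). Note that global
pairwise alignment of unrelated proteins yields noticeably *higher*
percent identity than the same pair inside a conservative multiple
alignment, so MSA input is preferred for clading and the threshold should
be read relative to the identity convention in use.

### Motif scanning (`locate_motif_anchors`, `extract_triads`)

The palm domain of a viral RdRP carries three catalytic motifs in fixed
order: motif A (conserved aspartate), motif B (two conserved glycines),
motif C (the catalytic triad around a central aspartate). The scanner is a
conservation heuristic over an input protein alignment: a column is an
anchor candidate when ≥ `min_frac = 0.7` of rows carry the diagnostic
residue (gaps count against); spacing constraints `min_AB_gap = 20` and
`min_BC_gap = 5` columns reflect typical palm-domain architecture; the
glycine pair may be adjacent or up to 3 columns apart, adjacent preferred.
Among valid motif-C candidates the highest D-frequency wins, ties toward
the smallest column. An alignment with no qualifying columns returns a
no-anchor result, not an error. Users reproducing a published,
structure-guided alignment can bypass the heuristic by passing explicit
anchor columns to `extract_triads` — structural alignment itself is out of
scope here.

The triad of each row is read at columns `(colC − 1, colC, colC + 1)`;
gaps render as `-` and mark the call `incomplete`. Classification against
a configurable catalog distinguishes `canonical` (GDD), `known_rare`
(SDD, GDN) and `novel` — the interesting outcome for divergent clades,
which is why the catalog is data, not code. `triads_by_clade()` makes
claims like "GDQ is exclusive to one clade" a computable cross-tabulation.

### Segment association (`associate_segments`)

Three evidence streams, each nullable, are combined by an explicit rule
set (`association_rules()`):

* **STRONG** — terminal conservation: ≤ 2 mismatches over both the first
  and last `k = 20` nt (positional comparison, no alignment, both
  sequences plus-sense). The `k` and the tolerance accommodate the
  observed one-mismatch-in-twenty case while excluding random termini,
  which mismatch at 15/20 on average.
* **MODERATE** — exact presence/absence co-occurrence across isolates with
  ≥ 2 shared positives. Presence is `Ct ≤ 38`; blank is absent. A single
  shared positive is uninformative, hence the floor of 2.
* **WEAK** — Pearson r ≥ 0.9 of `log10(count + 1)` over ≥ 3 libraries
  (libraries where both segments are absent are dropped; the log scale is
  required because counts span orders of magnitude).

A pair is `associated` with one STRONG stream, or with both MODERATE and
WEAK. Correlation alone never suffices: co-amplification across libraries
is common for co-infecting but unrelated viruses. Because the 5' and 3'
ends may behave differently, both terminal counts are computed and
reported separately, and the rule requires both.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` emits the full input bundle from one integer seed:
host contigs (database hits, sense-only reads) and bisegmented viruses —
an RdRP contig with planted A/B/C motifs at fixed protein offsets, paired
with a companion contig sharing `terminal_k = 20` nt termini — with reads
on both strands at a per-virus `plus_fraction` (default 0.7), Poisson
depth 200 per positive sample, 150-nt single-end reads, error rate 0,
4 samples, and per-virus presence drawn as *distinct* non-empty sample
subsets, emulating co-segregation panels in which each virus occupies its
own isolate set. Ct values are Uniform(20, 30) when present, blank when
absent. A planted protein alignment (rows padded with trailing gaps) ships
with each bundle so the motif stage is exercisable without an aligner.

The generator reproduces the *statistical structure* the pipeline decides
on — hit presence, strand mixture, terminal identity, co-segregation,
abundance coupling — not the texture of real data: no quality scores,
indels, chimeras, repeat-induced multi-mapping, uneven coverage, or hosts
with genuine antisense transcription (though `host_plus_fraction < 1`
creates such hard negatives on demand). Passing the recovery suites
therefore demonstrates that the decision rules are implemented correctly
and are mutually consistent, not that they are robust to every artifact of
real libraries.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; 1-based inclusive in all
  human-readable reports.
* FASTA characters outside `{A,C,G,T,N}` (IUPAC ambiguity codes) become
  `N` with a warning; duplicate ids and empty sequences are hard errors.
* Ct tables accept decimal commas ("24,67"), as printed by European-locale
  qPCR software; count tables strip thousands-separator commas
  ("132,412") — two readers, two documented dialects.
* Jaccard of two empty presence sets is defined as 0, with a warning.
* Correlation is `NA` (never a number) under 3 usable libraries or for a
  constant vector.
* All tie-breaks (motif columns, clade labels, ORF ordering) are
  deterministic, and re-running any stage on identical inputs is
  byte-identical; `summary.json` echoes every threshold in effect.
* Generator randomness flows from a single integer seed; the global RNG
  state is saved and restored around every seeded block.

## Problem sizes in the shipped tests

The test suite runs entirely on synthetic data plus the small printed
tables shipped as extdata: bundles of 3 viruses × 4 samples at depth 200,
twenty-seed recovery sweeps, 200 random 300-nt sequences against the ORF
enumeration oracle, 100 random matrices against a BFS component oracle,
and 50 random protein pairs against an independent Gotoh dynamic program.
These sizes give stable pass/fail behaviour on a single CPU in a few
minutes; all are ordinary parameters, so larger sweeps are a loop away.

Two checks verify deposited GenBank records (segment lengths, the 966-aa
115.74-kDa RdRP, the one-mismatch termini, ≥ 3 clades) and run only when
those FASTA files are placed under `inst/extdata/genbank/`; the package
does not redistribute them.

## Known limitations

* The clade threshold is convention-dependent (see above); clading raw
  proteins through the built-in pairwise aligner and through an external
  MSA are not numerically comparable.
* Motif anchoring by conservation requires a reasonable alignment and ≥ 2
  sequences; a single novel RdRP cannot be motif-anchored without an
  external reference alignment.
* Strand decoding trusts the declared protocol; there is no internal
  consistency check against, e.g., annotated host mRNAs.
* The association rules are a formalization of evidence streams that are
  usually weighed narratively; the defaults are conservative, and every
  threshold is configurable and echoed into the output for exactly that
  reason.
* Satellite RNAs versus genuine genome segments cannot be distinguished
  from these data alone; resolving that requires isolate panels beyond
  co-occurrence.
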