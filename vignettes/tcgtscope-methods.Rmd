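---
title: "Models and methods behind tcgtscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcgtscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological setting

Transposable-element-embedded regulatory sequences (TEeRS) — above all the
long terminal repeats (LTRs) of endogenous retroviruses — supply promoters
and enhancers that become active during the epigenetic reprogramming of
gametogenesis and early embryogenesis. Two observable consequences organize
this package:

* **Transpochimeric gene transcripts (TcGTs)**: transcripts that initiate
  inside an LTR and splice into an annotated gene, so that the TE acts as an
  alternative promoter. Subfamilies such as LTR12C (the ERV9-associated LTR)
  dominate this activity in oocytes and around zygotic genome activation
  (ZGA).
* **KRAB zinc finger protein (KZFP) control**: sequence-specific repressors
  whose binding (measurable as ChIP enrichment over TE subfamilies)
  coincides with the retention of CpG methylation at their target loci
  through the genome-wide demethylation of primordial germ cells.

`tcgtscope` re-implements the computational machinery needed to observe both
phenomena — TcGT calling and enrichment, repeat-annotation curation, peak
and proximity enrichment, expression-pattern clustering, per-locus
methylation profiling, alignment signal profiles and cross-species
similarity scoring — and couples it to a seeded synthetic-data generator
whose planted ground truth makes every stage falsifiable.

## Coordinate conventions

All in-memory intervals are `GRanges`: 1-based, closed, the universal
Bioconductor convention. Disk formats keep their native conventions and are
converted only in the readers and writers: BED and CpG positions are 0-based
half-open on disk, RepeatMasker `.out` and GTF are 1-based inclusive. Using
one in-memory convention everywhere (and the interval machinery that comes
with it) is what prevents off-by-one drift; the boundary behaviours that
matter — an exon *abutting* a TE does not overlap it, a TSS one base outside
an LTR is not inside it — are pinned by tests.

## Repeat-catalog curation

RepeatMasker fragments single insertions into multiple records, and
full-length ERVs are annotated as LTR–internal–LTR triplets. Curation
proceeds in three steps:

1. **Fragment reassembly** (`merge_fragments`): records sharing a
   RepeatMasker integrant id, or lying on the same chromosome, strand and
   subfamily within `max_gap` (default 100 bp), are merged into one locus
   spanning the outermost coordinates. Merging uses a union–find over
   adjacency and linkage edges; because a merged span's endpoints are
   endpoints of original records, the operation is idempotent.
2. **Full-length ERV assembly** (`assemble_full_length_ervs`): an LTR
   adjacent (default `max_gap` 500 bp) to an internal segment it is paired
   with (e.g. LTR12C with HERV9 internals) is merged into a single feature
   labeled by the internal subfamily. The two gap defaults differ because
   fragment gaps are alignment artifacts (tens of bp) while LTR/internal
   boundaries include annotation slack; both are configurable.
3. **Solo-LTR flagging and exon exclusion**: an LTR-class locus not merged
   with any internal segment is a solo LTR — the operational rendering of
   the recombination product that retains the promoter but no coding
   sequence. Loci overlapping an annotated exon by even one base are
   discarded before any counting, since exonic reads cannot be attributed
   to TE activity.

## TcGT calling and enrichment

A transcript model is a TcGT when three predicates hold: its strand-aware
TSS base lies **inside** an LTR-class locus; it has at least one splice
junction (assembled transcript models encode the "minimum one read spanning
the junction" evidence as the junction itself); and at least one
downstream-of-junction exon overlaps an annotated gene exon. The cognate
gene maximizes total downstream exonic overlap, with ties broken by the
lexicographically smallest gene id. Calls for the same gene and driver
subfamily whose TSSs fall within 100 bp of one another — directly or
through intermediates (single linkage) — are aggregated, and the 5'-most
member represents the aggregate.

Enrichment per sample group asks whether the distinct driver loci observed
in the group over-represent a subfamily relative to the curated catalog:
with $k$ drivers of the subfamily among $n$ drivers overall, $K$ catalog
loci of the subfamily among $N$, the p-value is the hypergeometric upper
tail $P(X \ge k)$, Benjamini–Hochberg-adjusted across subfamilies *within
each group*. Loci (not aggregates) form the universe because the catalog —
the natural background — is a set of loci; one-sided tests are used
throughout the enrichment contexts because the question is
over-representation.

## Peak enrichment, consensus and proximity

A ChIP peak is attributed to the TE locus it overlaps most, but only when
the overlap strictly exceeds half the peak length. Subfamily enrichment
compares the number of attributed peaks with a uniform-placement
expectation, $p_0 = \text{subfamily bp}/\text{genome bp}$, through the
one-sided exact binomial tail — the genomic-size correction that keeps
large, old subfamilies from appearing enriched by mass alone. Each peak is
one trial; peak width is not modeled, which makes the null conservative
(a peak must also clear the 50% rule to be attributed).

Consensus peaks keep the regions covered by at least two distinct
replicates and merge contributing peaks into their union. Proximity testing
classifies every gene by whether its TSS lies within 50 kb of a TE locus
(distance to the nearest locus edge, zero when overlapping) and applies the
two-sided Fisher exact test to the resulting 2×2 table.

## Expression normalization and temporal clustering

Counts on genes and TE loci are filtered (row sum at least the number of
samples), then scaled by TMM factors computed **on gene rows only**, with
gene-count sums as library sizes — TE counts, which are the quantity under
study and can be wildly stage-specific, must not influence the scaling.
The factors follow the published trimmed-mean-of-M-values recipe (30%
log-ratio trim, 5% intensity trim, inverse-variance weights, reference
chosen by upper quartile) as implemented in edgeR; an independent hand
evaluation of the formula backs the tests. Normalized values are
$\log_2(\mathrm{CPM}+1)$-transformed, z-scored per row (sample standard
deviation, $n-1$; constant rows become zero and are flagged) and clustered
hierarchically with distance $1-r$ (Pearson) and complete linkage, cut into
two groups. On data with maternal-style (high in oocyte/zygote, off after
cleavage) and ZGA-style (off early, on from the 8-cell stage) patterns the
two-group cut recovers exactly those clusters.

## Methylation profiling

Per-locus methylation is the unweighted mean of the CpG fractions inside
the locus — levels are averaged, not counts, so deeply covered CpGs do not
dominate. Loci without profiled CpGs are absent rather than zero.
Replicates are averaged where present; subfamily summaries average locus
means with equal weight per locus (the tests demonstrate on a two-locus toy
that this differs from the CpG-weighted mean whenever CpG counts differ).
Two locus sets (maternal vs ZGA clusters, KZFP targets vs non-targets) are
compared with the two-sided Wilcoxon rank-sum test: exact by enumeration
for pooled samples of at most 12 without ties, otherwise the midrank normal
approximation with tie and continuity corrections, with the branch
reported. No minimum-coverage filter is applied by default; the reader
accepts count pairs and computes ratios when given them.

## Alignment signal profiles

Externally computed gapped alignments are post-processed: columns with
strictly more than 85% gaps are trimmed (a column at exactly the threshold
stays); per-locus signal tracks are min–max scaled to $[0,1]$ (constant
tracks map to zero and are flagged); scaled tracks are projected onto
alignment columns (gaps become missing) and averaged column-wise over
non-missing values with a coverage count. Trimming precedes projection
because the plotted alignment is the trimmed one. Projection followed by
gap-stripping returns the input track exactly — the invariant that
guarantees no positional bookkeeping error.

## Cross-species scoring

TE-locus conservation across genomes is the fraction of the human sequence
covered by the pairwise alignment to the syntenic locus (substitutions
ignored), normalized by the subfamily **consensus** length and capped at 1 —
normalizing by the consensus rather than the locus keeps truncated
integrants from scoring as fully conserved. Syntenic loci are classified as
same-subfamily, same-family, unannotated (which also absorbs
divergent-family labels) or not detected; similarity is forced to zero
exactly when not detected.

KZFP relatedness uses the zinc fingerprint: the ordered quadruplets of
DNA-contacting residues (positions −1, 2, 3, 6 of each finger). Published
scorers for this comparison are proprietary, so the package declares its
own deterministic rule and labels it as such: global dynamic-programming
alignment of the finger sequences where matching two fingers scores their
fractional residue identity and skipping a finger costs 0.25, normalized by
the larger finger count and clamped to $[0,1]$. The score is symmetric and
equals 1 exactly for identical fingerprints; the gap cost is small enough
that a single finger insertion (a common KZFP event) costs 2.5% on a
ten-finger array rather than disqualifying the pair. KRAB-domain similarity
is left to an externally supplied metric and reported separately when
present.

## The synthetic study design

The generator (`sim_config`, `simulate_dataset`) emits a self-consistent
toy dataset from one integer seed; each stage draws from a deterministic
substream so regenerating one stage leaves the others untouched. Defaults
define the study conditions:

* **Genome and annotation**: two 5-Mb chromosomes; 120 three-exon genes;
  ~290 TE records over seven subfamilies, dominated by LTR subfamilies with
  full-length LTR–internal–LTR elements for LTR12C/HERV9 and LTR7/HERVH.
  Features are placed without overlap and with exclusion margins (600 bp
  TE–TE, 450 bp TE–gene) wider than every merge window, so curation can
  never fuse independent insertions. A quarter of records are fragmented
  into linkage-tagged pieces with 20–80 bp gaps.
* **Transcriptomes**: three groups (oocyte-, 8-cell-, morula-like) of three
  samples; 10 planted TcGTs per group, 80% driven by LTR12C (drivers placed
  700–2000 bp upstream of their genes); 60 decoys, each violating exactly
  one predicate; 30 background gene transcripts per sample.
* **Peaks**: 500 peaks of 200 bp, 40% placed fully inside LTR12C loci, the
  rest uniform; three replicates with ±20 bp jitter and 90% per-replicate
  presence.
* **Expression**: six stages × two replicates; 30 maternal and 30 ZGA
  loci; negative-binomial counts (size 100) around
  $2^{\log_2 50 + 5\,T + \varepsilon}$ with the template $T \in \{0,1\}$
  and $\varepsilon$ Gaussian with sd expressed as a fraction (default 0.1)
  of the 5-log2 amplitude; gene rows with stage-independent means exercise
  TMM.
* **Methylation**: two disjoint sets of 50 solo-LTR loci with locus levels
  Beta-distributed around 0.7 and 0.4 (concentration 10), CpGs every 40 bp
  scattered around the locus level (concentration 30), two replicates.

What the toys do **not** emulate: nucleotide sequence (no composition or
alignment realism), read-level noise (no FASTQ/BAM, no mapping ambiguity or
multi-mapping), overlapping or nested insertions, copy-number realism of
real repeat families, biological covariation between stages beyond the two
templates. Passing tests therefore demonstrate the correctness of the
*computational contracts* — predicate logic, boundary behaviour, exactness
of statistics, calibration and power under the planted model — not
performance on real sequencing data.

## Numerical and degenerate-input choices

* Hypergeometric/binomial tails come from `phyper`/`pbinom` (exact to
  machine precision); Fisher's two-sided p sums fixed-margin tables whose
  probability does not exceed the observed (with the customary
  $1+10^{-7}$ slack); BH adjustment is the step-up formula capped at 1.
* The exact rank-sum branch refuses ties and pooled sizes above 12,
  falling back to the tie-corrected normal approximation with continuity
  correction.
* Zero-variance rows cannot enter a correlation distance; they are
  assigned after cutting to the nearest (Euclidean) centroid and flagged.
* `hclust` with complete linkage is deterministic for the distances the
  pipeline produces; row order invariance is asserted in tests.
* Degenerate proximity tables (a column of zeros) return p = 1 rather than
  erroring; empty gene sets and overlapping methylation sets are errors.

## Problem sizes used in validation

The test suite validates statistics against brute-force enumeration for all
population sizes up to 12 (500 random parameterizations each for the
hypergeometric and Fisher tests, 150 rank-sum enumerations, 1000 BH
vectors), and runs the planted-recovery checks at the default study
conditions: the seed-42 fixture for TcGT recovery; 200 simulated peak sets
each under the null and the planted fraction; 50 expression simulations at
each noise level; 50 planted and 200 null methylation simulations; and 100
reduced catalogs (≈60 records each) for the fragmentation round trip.
These sizes keep the whole suite to a few minutes on one core while leaving
each check enough replicates for its stated error bound.

## Known limitations

* The TcGT caller consumes assembled transcript models, not alignments;
  junction read support must have been enforced upstream.
* TMM factors are only approximately invariant to rescaling a single
  library (the inverse-variance weights see absolute depth); the
  compositional contracts (identical and proportional libraries give unit
  factors) are exact.
* The fingerprint score is a declared stand-in, not a reproduction of any
  proprietary scorer; absolute values should not be compared across
  scoring rules.
* Nested or overlapping TE insertions are not merged or resolved; the
  curation assumes RepeatMasker-style linear fragmentation.
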