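---
title: "srnapipe: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnapipe: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

This vignette is the package's own account of what it computes and why the
open design questions were settled the way they were. The companion README
shows the end-to-end workflow; here the emphasis is on the models, their
assumptions, and the numerical details a careful user should know.

## Coordinate model

All intervals inside the package are **1-based, closed** — the native
GFF/GenomicRanges convention — and all interval arithmetic is delegated to
IRanges/GenomicRanges. The distance between two features is the gap in
nucleotides between their closest ends: overlapping *and* directly abutting
features are both at distance 0. "At least 30 nt away" is therefore the
inclusive condition gap ≥ 30. Using the Bioconductor containers directly
(rather than a package-private half-open convention) means one conversion
at the file boundary and none internally, and every overlap/gap computation
is the battle-tested library one.

## Classification geometry

A transcript is classified against the *effective* gene set of its contig:

* Small-peptide discounting: a gene shorter than `small_peptide_max`
  (100 nt) lying fully within the transcript is removed when the transcript
  is *strictly* more than `small_peptide_transcript_ratio` (3) times the
  gene length. The strictness matters at the boundary: a 90-nt gene inside
  a 280-nt transcript is discounted (280 > 270), inside a 270-nt transcript
  it is not.
* Labels: *coding* on any same-strand overlap; *intergenic* when the
  nearest gene on either strand is ≥ `min_gene_distance` (30 nt) away;
  *antisense* when every same-strand gene is ≥ 30 nt away and some
  opposite-strand gene overlaps by ≥ `min_antisense_overlap` (10 nt);
  *ambiguous* otherwise. Ambiguous records are retained and flagged, never
  silently dropped, so the catalog accounts for every input transcript.
* When several opposite-strand genes overlap an asRNA, all are recorded;
  the primary partner is the largest overlap, ties broken by gene id.

A transcript with no gene anywhere on its contig is intergenic: "infinitely
far" satisfies any distance bound.

## Reading-frame filter

The noncoding criterion is that no reading frame may exceed
`max_orf_fraction` (one third) of the transcript length. "Reading frame" is
implemented as the longest stop-codon-free stretch (TAA/TAG/TGA; `N` never
forms a stop), in nt, over all six frames — deliberately *not* requiring an
ATG, since short peptides in poorly annotated communities often lack
canonical starts and the filter is meant to be conservative about coding
potential. An ATG-initiated variant is available via
`pipeline_config(orf_method = "atg")` for users who prefer the classical
definition. The implementation is validated against a brute-force
enumeration oracle on 1,000 random sequences of 50–500 nt in the test
suite.

## Contig-edge correction

Transcripts assembled at contig tips are frequently truncation artifacts.
The package chooses the minimum edge distance *dynamically*: on the grid
d ∈ {0, 10, …, 500} nt it compares the number of candidates with edge
distance < d against the uniform-placement null, in which a candidate lands
within d of an end with probability

p₀(d) = Σ_c min(2d, L_c) / Σ_c L_c,

using the exact one-sided binomial tail. Because the grid is scanned as a
family (50 correlated, nested tests), each test runs at level
`edge_alpha`/m (Bonferroni, m non-zero grid points); without that
correction the scan would flag tip enrichment in roughly a fifth of
null data sets, defeating its purpose of firing only when candidates
really pile up at contig ends. The chosen threshold is the smallest grid
distance beyond which no test is significant; all candidates closer than it
are flagged `edge_fail`. A two-sided variant is available
(`edge_sided = "two"`), though depletion at contig tips has no artifact
interpretation and the one-sided enrichment tail is the default. Test-suite
calibration: under uniform placement (100 replicates, 400 candidates on
20 × 2 kb contigs) the threshold exceeds 0 in at most a few percent of
replicates; with candidates 3× enriched within 50 nt of the edges it
reaches ≥ 50 nt essentially always.

## Filter order and provenance

Stages run classification → edge → length → reading frame → coverage →
protein homology → Rfam. Cheap geometric filters come first; the order is
recorded in the catalog's provenance log as (step, n_in, n_out) with
telescoping counts, so any reordering is auditable. Flags accumulate on the
records rather than removing them; the *surviving* regulatory set is the
records labeled intergenic/antisense with no flags, and the *ncRNA catalog*
additionally keeps Rfam housekeeping RNAs (tRNA, RNase P, SRP) that are
excluded from the regulatory tier — known noncoding RNAs are evidence the
pipeline works, not noise to discard.

## Homology thresholds: strict vs inclusive

The protein-homology exclusion requires a *single* hit to satisfy all four
conditions simultaneously — query cover > 30%, bitscore > 50, E < 1e−4,
identity > 30% — with strict inequalities, so a hit sitting exactly on any
bound does not flag. The nucleotide-conservation annotation uses inclusive
bounds (E ≤ 1e−3, identity ≥ 70%, cover ≥ 50%), so a hit exactly at all
three bounds *is* conserved. Query cover is always recomputed by the reader
from |qend − qstart| + 1 over the query length, making minus-orientation
hits and BLAST dialects behave identically; whether conservation coverage
refers to the query or the subject is switchable
(`cons_cover_on`, default query — the sRNA is the biological unit whose
conservation is being asked about).

## Expression model

**Contig normalization.** The quantity of interest is transcript-level
regulation, not organism abundance. Each transcript count is divided by the
total count of its parent contig and scaled by `count_scale` (10⁶ —
"counts per million of parent-contig reads"). Multiplying a contig's reads
in one sample by any factor (transcript and contig rows alike) leaves the
normalized value unchanged; that invariance *is* the operation's purpose
and is asserted in the tests. A transcript count of 0 normalizes to 0; a
positive transcript count on a zero-count contig is rejected as
inconsistent input.

**Differential expression.** Features are modeled as negative binomial with
Var = μ + αμ². Because normalized counts live on an arbitrary scale, the
model is estimated in *relative* form: the squared coefficient of
variation obeys CV² = 1/μ + α, so the package takes the pooled
within-group moment estimate s²/μ̄², fits the cross-feature trend
b₀ + b₁/μ by least squares (b₁ absorbs the count scale, making every
downstream decision exactly invariant to `count_scale`), and shrinks the
per-feature log CV² toward the trend with prior weight 3 (pseudo-degrees
of freedom against the n₁+n₂−2 data degrees). The Wald statistic is the
log₂ fold change (group 2 over group 1; for character designs the groups
are taken in alphabetical order, for factors in level order) over its
delta-method SE, referred to a **t** distribution with n₁+n₂−2 df — at
10 + 10 replicates the normal reference is visibly anticonservative while
the t reference holds the nominal level. Multiplicity is controlled by
Benjamini–Hochberg over tested features; all-zero features are excluded
and reported NA. Degenerate cases: identical counts give log₂FC 0 and
p ≈ 1; a feature expressed in only one group uses a scale-equivariant
pseudo-mean (half the smallest positive value in the matrix) for the fold
change so its statistic stays finite.

This test is *not* intended to reproduce DESeq2 bit for bit; it is accepted
by calibration — type-I error within the binomial band around 5% on null
simulations, ≥ 80% sensitivity at FDR ≤ 5% for planted |log₂FC| = 2, and
empirical FDR ≤ 10% — and by the confounding control below.
`write_expression_table(..., round = TRUE)` exports integer-rounded
normalized counts for users who want to run an external count-based tool
instead.

**The headline property** separating this pipeline from naive DE: a planted
4-fold contig-abundance shift with zero transcript effects produces no
excess significant calls after normalization, and floods the test (~half of
all features) when normalization is bypassed. This is asserted in the
acceptance tests and recomputed by `scripts/acceptance.R`.

## Community analytics

* **Taxonomy.** A "weighted average" of categorical lineages is undefined;
  it is operationalized as a rank-by-rank weighted majority vote with gene
  length as the default weight. The lineage descends while the winning
  name holds ≥ 0.5 of the informative weight at that rank; an exact
  0.5/0.5 tie keeps the lexicographically first name and is flagged as a
  tie. Each sRNA inherits the lineage of its contig.
* **Overlap geometry.** The asRNA/gene overlap is projected onto the mRNA
  axis oriented 5′→3′ (for a minus-strand gene position 0 is its right
  edge), reported as fractions of gene length — mirror-symmetric by
  construction.
* **Correlation.** Pearson r with the exact t-based two-sided p (n−2 df)
  on expression tracked across shared replicates, standardized TPM
  recommended; significant at p < `corr_alpha` (0.01). Zero-variance
  profiles are reported NA rather than ±1.
* **Upstream regions.** `upstream_len` (50 nt) immediately 5′ of the
  transcript start, reverse-complemented for minus-strand records,
  truncated (and flagged) at contig edges; emitted as FASTA for external
  motif tools.
* **Interaction density.** From an externally produced sRNA–target table,
  the top `top_n_interactions` (100) records ranked by ascending p-value
  (ties: lower energy, then target id) contribute their spans to a
  per-position count along the sRNA; the peak is the first position of
  maximal density. Ranking by lowest hybridization energy is available via
  `rank_by = "energy"` — both ranking conventions appear in practice, and
  p-value is the default because it reflects the significance model rather
  than raw thermodynamics.

## The synthetic community: what it does and does not emulate

`generate_community()` emits an assembly, annotation, transcripts and a
truth table with every planted label, margin and expected flag, plus decoys
exactly one nt inside each rule boundary (29/30 nt gaps, 9/10 nt overlaps,
49/50/500/501 nt lengths, 4.9/5.0 and 9.9/10.0 coverage, the 3:1
small-peptide boundary, a full-length open frame). Planted noncoding
sequences are tilings of a 15-mer cassette chosen so that the longest
stop-free stretch in *all six frames* is at most 12 nt, guaranteeing
passage of the one-third filter by construction rather than by rejection
sampling against the code under test. All features keep ≥ 600 nt from
contig ends so the edge scan is exercised by its own dedicated
simulations. `generate_counts()` draws NB counts in the same
mean–dispersion parameterization the DE module estimates, with
contig-level abundance shifts applied multiplicatively to every feature of
a contig in group 2 and transcript-level effects to single transcripts —
the two causes of expression change the normalization is meant to
separate.

What the generator does **not** emulate: sequencing-error and read-level
noise (no FASTQ), fragmented or chimeric assemblies, overlapping operonic
transcription, strand bleed-through in library preparation, compositional
taxon structure, or database-dependent homology (protein/Rfam hits are
supplied as toy tables at the printed thresholds). Passing the planted
truth therefore demonstrates that the *rules are implemented exactly as
stated* and that the statistics are calibrated under their assumed models —
not that real metatranscriptomes will be this clean.

## Problem sizes and runtime

The test suite and the acceptance script were sized for quick desk runs:
a 5-contig community with ~200 planted sRNAs for recovery; 1,000 random
sequences for the reading-frame oracle; 100 Monte-Carlo replicates of
400 candidates for the edge scan; 2,000 features at 10 + 10 replicates for
DE calibration; 1,000 features on 100 contigs for the confounding control;
2,000 pairs for correlation calibration. The full suite runs in about a
minute; the acceptance script in a few seconds.

## Known limitations

* Transcripts are treated as single-exon (prokaryotic/archaeal model);
  exon rows in GTFs are ignored and no splice awareness exists.
* Counting, alignment, assembly, and all database searches (BLAST,
  Infernal, hybridization prediction, motif discovery) run upstream or
  externally; only their tabular outputs are consumed.
* The DE model is two-group with contig normalization in place of
  size-factor estimation; multi-factor designs and fold-change shrinkage
  are out of scope.
* The edge-scan null assumes candidates are placed independently and
  uniformly; strong operonic clustering would violate it in either
  direction.
* Taxonomy support values are vote fractions, not probabilities; a 0.51
  majority on two genes is reported just like one on fifty.
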