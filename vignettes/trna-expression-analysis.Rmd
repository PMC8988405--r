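---
title: "Analysing tRNA expression with isodecodeR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing tRNA expression with isodecodeR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodecodeR)
```

## The problem

Mammalian genomes carry large, redundant families of tRNA genes. Many
loci within a family encode byte-identical mature sequences, so a
sequencing read — even a full-length read from a protocol such as
YAMAT-seq that captures the mature tRNA via its 3' CCA tail — cannot be
attributed to one locus. Aligners "solve" this by multi-mapping; counting
multi-mapped reads per locus then double-counts or arbitrarily splits
them. `isodecodeR` instead makes the ambiguity explicit: loci with
identical mature sequences are collapsed into a *sequence group*
(`collapseIdenticalSequences()`), and every downstream quantity —
expression flags, differential expression, anticodon profiles — is
defined at group level. `assignReads()` embodies the same idea for raw
reads: after stripping a terminal CCA (the tail is post-transcriptional,
so it is never part of the genomic mature sequence), a read of length
at least 50 nt either matches exactly one group sequence or is
unassigned; no read can be counted twice.

Mature sequences are the genomic sequence of the annotated span with
intron (exon-gap) segments removed, reverse-complemented for minus-strand
genes, and transliterated to the RNA alphabet. The anticodon is always
taken from the annotation attributes (the GtRNAdb-style identifier token
`tRNA-<AA>-<anticodon>-<n>-<m>`, with explicit `amino_acid`/`anticodon`
attributes as fallback), never inferred from sequence position. When
annotation totals are reported, the default counts every record in the
file; a `high_confidence_only` flag restricts to non-pseudogene,
non-secondary-filtered predictions, since published genome-wide totals do
not always state which convention they use.

## Expression filtering

A feature is *expressed* in a tissue iff its **raw** count is positive in
at least `min_individuals = 2` distinct individuals of that tissue.
Two choices deserve comment:

* "Counts present" is read as raw count > 0, not as a CPM threshold —
  the CPM ≥ 5 rule belongs to the differential-expression prefilter,
  which is a different question (is a feature *quantifiable*, not merely
  *detected*).
* Individuals are identified by the `individual` design column, not by
  sample id, so technical replicates of one animal can never satisfy the
  rule.

Flags can additionally be stratified per treatment-within-tissue
(`within = "treatment"`); the same `min_individuals` default applies
there, as the published per-treatment totals do not state a separate
threshold. Gene-level flags inherit from the gene's sequence group
(`geneFlagsFromGroups()`): a locus counts as expressed iff any
identical-sequence locus shows reads, because locus-level attribution is
impossible inside a group. `isodecoderExpressedProportion()` then divides
expressed gene copies by annotated copies per anticodon and tissue.

## Differential expression

The testing stack mirrors the classic count-based DE machinery but is
implemented here from its definitions:

* **Prefilter** — keep a sequence group iff CPM ≥ `cpm_threshold = 5`
  (inclusive) in *all* control samples, or *all* ART-normal samples, or
  at least `los_min = 2` ART-LOS samples. The LOS clause's group size is
  not fixed by the design, so `los_min` is configurable with default 2.
* **TMM factors** — reference column = the one whose upper-quartile
  count fraction is closest to the mean upper quartile (lowest index on
  ties); log2 count-fraction ratios M trimmed 30 % per side, mean
  abundance A trimmed 5 % per side; precision-weighted mean of the
  surviving M values; factors rescaled to geometric mean 1. All-zero
  columns get factor 1 with a warning.
* **Dispersion** — a pooled method-of-moments estimate of φ in
  Var = μ + φμ², computed per group on counts rescaled to a common
  effective library size and combined as
  Σ(n−1)(v−m) / Σ(n−1)m², floored at 0. This deliberately replaces
  likelihood-based dispersion machinery: numerical agreement with any
  particular DE package is *not* a goal; the estimator is validated by
  parameter recovery and by the type-I error of the test it feeds.
* **Exact test** — counts are rescaled to the geometric-mean effective
  library size with deterministic half-up rounding; under the null the
  group-A sum conditioned on the total follows the convolution ratio of
  two negative binomials with common φ (sizes n_A/φ and n_B/φ), a
  binomial split when φ = 0. The two-sided p-value sums the probability
  of every outcome at most as likely as the observed one (with a 1e-10
  relative slack against floating-point ties); all-zero features get
  p = 1, and p is clamped into (0, 1].
* **FDR and calling** — Benjamini–Hochberg step-up, implemented
  directly; a group is called iff p ≤ α *and* FDR ≤ α with α = 0.05,
  both inclusive. Fold changes are log2 of mean CPM ratios with a 0.5
  pseudocount to avoid infinities; results list all member loci of each
  group, since any of them could be the transcriptional origin.

Unwanted-variation correction (RUV-style factors) is not re-implemented —
it requires negative-control features the analysis cannot choose by
itself — but `deTest(offsets = ...)` accepts externally computed
per-sample factors in place of TMM.

## Codon usage and concordance

`codonFrequencies()` counts in-frame codons per CDS, excluding a terminal
stop, skipping codons with ambiguity letters, flagging internal stops in
a QC table and skipping (with a warning) sequences whose length is not a
multiple of 3. RSCU follows the classical definition — observed count
divided by the family-uniform expectation, so Σ RSCU = family size —
and relative adaptiveness (RAC) divides by the family maximum. Per-group
profiles average per-gene values unweighted across expressed genes
(≥ `min_tpm = 1` TPM in ≥ `min_reps = 2` replicates, both inclusive);
genes in which a family is entirely absent are excluded from that
family's average rather than counted as zero, because zero-filling
short genes would systematically drag averages down. A pooled-counts
mode is provided for comparison since either reading of "averaging the
per-gene values" is defensible.

Anticodons (RNA, 5'→3') map to codons (DNA) by reverse complement at the
pairing boundary only. Wobble decoding at position 34 follows
G34 → C/U, U34 → A/G, C34 → G, and A34 → U, extended to U/C/A when A34
is treated as inosine (the default, as A34 is almost universally
deaminated). This is why, e.g., a proline family with no GGG-anticodon
gene still decodes the CCC codon. `concordance()` compares the
Watson–Crick codon of each family's top-expressed anticodon with the
family's most frequent codon; families with no expressed anticodon are
excluded from the denominator and listed.

## Correlations and partitions

Expression values entering correlations are per-anticodon mean CPM over
the relevant samples (a log2 option exists but defaults off). Pearson r
carries a two-sided p-value from the t-distribution with n − 2 degrees
of freedom; constant vectors are a hard error rather than a silent NA.
For the usage/expression correlation both sides are first rescaled to
percentages within each amino-acid family (so each family totals 100),
and anticodons with no annotated gene are excluded rather than
zero-filled — they are unannotated, not observed-at-zero. The
copy-number correlation accepts a drop list so high-copy families can be
removed as a sensitivity analysis. Whether such correlations should use
per-sample points or per-anticodon means is genuinely open; the default
is per-anticodon means over a sample subset, which is what the helper
`anticodonMeanCpm()` produces.

## DMR proximity

BED input is 0-based half-open and converted to 1-based inclusive on
read. Distance between a gene and a DMR is 0 on overlap (relation
`overlap_gene_body` when the DMR intersects the gene span) and otherwise
the difference between the nearest interval ends; strand is ignored. The
window is inclusive: "within 5 kb" admits a pair at exactly 5,000 bp,
and the boundary is unit-tested explicitly on both sides. Every reported
pair carries the size of the gene's sequence group, because a methylated
locus inside a large identical-copy group cannot be assigned locus-level
expression changes. Inputs must share one assembly; no liftover is
attempted.

## The synthetic-data generators

The generators emulate the study conditions: 2 tissues × 3 treatment
groups with 13 animals per tissue (5/4/4 per treatment — per-treatment
group sizes are not fixed by the published design, so they are
configurable), the same animals providing both tissues; library sizes
log-uniform over 0.5–2 × 10⁶ so that CPM and TMM are exercised
non-trivially; negative-binomial counts with configurable φ (default
0.1, a typical bulk-count overdispersion); random 72–90 nt mature
sequences with a configurable fraction of exact duplicates per
anticodon; CDS sets as ATG + weighted codon draws + stop; DMRs planted
at exact distances from chosen genes, re-drawn when another gene would
sit closer. For the `independent` copy-number relation the expected rate
is drawn per *anticodon* and split across its groups — drawing rates per
group would mechanically correlate summed anticodon expression with copy
number and defeat the null.

Every generator is a pure function of its parameters and seed, and its
truth record (group map, silenced sets, spiked fold changes, planted
distances, per-gene codon tallies) is what the tests check recovery
against. What the generators do **not** emulate: reverse-transcription
stalling at modified bases and the resulting truncations, sequencing
error, adapter artefacts, or correlated per-sample effects beyond
library size. Passing tests therefore demonstrate that the analysis
recovers known structure from idealised count data, not that it is
robust to tRNA-seq's modification-induced biases.

## Numerical choices and problem sizes

* log2 CPM uses log2(CPM + 1); the pseudocount preserves zeros.
* Unassigned reads are excluded from library sizes, matching a
  feature-restricted counting workflow.
* Exact-test enumeration runs over the full conditional support up to
  totals of 10⁵ and over a ±60-standard-deviation window beyond that.
* Ties in TMM reference selection and preferred-codon argmaxes break
  deterministically (lowest index / lexicographic).
* Validation problem sizes were chosen to make each statistical check
  informative while keeping the whole suite quick: 1,000 features for
  type-I error (so a ±0.02 band is ~3 binomial SDs), 300 features with
  10 four-fold spikes over 20 seeds for power, 500 features for
  dispersion recovery, 1,000 random vectors for the BH oracle.

## Limitations

* Group-level DE cannot localise a change to a locus; the member list is
  the honest answer.
* The moment dispersion estimator is unshrunk; with very few samples it
  is noisy, which the conditional test partly absorbs.
* The wobble table is the standard eukaryotic rule set; organism-specific
  modifications (e.g. 5-position uridine modifications restricting
  U34 pairing) are not modelled.
* Selenocysteine and initiator-methionine tRNAs are carried as distinct
  labels and excluded from the 20-family codon analyses.
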