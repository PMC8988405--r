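# isodecodeR

Analysis of bulk tRNA-seq experiments (e.g. YAMAT-seq) in species whose
genomes carry hundreds of near-identical tRNA gene copies. Mammalian
genomes — cattle in particular, with well over a thousand annotated tRNA
loci — contain multicopy tRNA families in which many loci encode
byte-identical mature sequences, so a sequenced read can never be
attributed to a single locus. `isodecodeR` resolves this by collapsing
identical-sequence loci into *sequence groups* and carrying out the whole
expression analysis at that level: expression filtering, differential
expression between treatment groups, codon-usage concordance,
copy-number and codon-usage correlations, and proximity of differentially
methylated regions (DMRs) to tRNA loci.

## What it computes

* **Annotation handling** — parses tRNAscan-SE / GtRNAdb style GFF3 plus a
  genome FASTA into a `TrnaGeneSet` (mature sequences intron-spliced,
  reverse-complemented, RNA alphabet, no 3' CCA), builds per-anticodon
  copy-number tables, and reports anticodons with no high-confidence gene
  copy.
* **Sequence collapsing** — `collapseIdenticalSequences()` partitions loci
  by exact mature sequence into `SequenceGroups`, the unit of all
  downstream quantification.
* **Quantification** — CPM normalisation; a feature is *expressed* in a
  tissue iff its raw count is positive in ≥ 2 distinct individuals of
  that tissue; per-anticodon proportions of expressed gene copies.
* **Differential expression** — re-implementation of the classic
  count-based testing stack: TMM normalisation factors, a pooled
  method-of-moments estimate of the common negative-binomial dispersion
  φ (Var = μ + φμ²), a two-sided conditional exact test of the group-A
  sum given the total (binomial split when φ = 0), Benjamini–Hochberg
  step-up FDR, and calling at p ≤ 0.05 ∧ FDR ≤ 0.05. The prefilter keeps
  a feature iff CPM ≥ 5 in *all* control samples, or *all* normal
  samples, or ≥ 2 LOS samples.
* **Codon usage** — codon frequencies from CDS sets restricted to
  expressed genes (≥ 1 TPM in ≥ 2 replicates), RSCU
  (count / family-uniform expectation) and relative adaptiveness
  (count / family max), Watson–Crick and wobble anticodon→codon maps
  (G34→C/U, U34→A/G, C34→G, A34-as-inosine→U/C/A), preferred codons and
  per-family concordance between the top-expressed anticodon and the most
  frequent codon.
* **Correlations & partitions** — Pearson r with t-distribution p-values
  (n − 2 df) for expression vs copy number and family-percentage RSCU vs
  anticodon expression; shared/unique membership partitions across
  tissues and treatments.
* **DMR proximity** — BED intervals against tRNA loci within an inclusive
  5 kb window, with the identical-locus ambiguity count attached to every
  pair.
* **Synthetic data** — seeded generators (annotation, counts, reads, CDS
  sets, DMRs) whose recorded ground truth every pipeline stage must
  recover; the default design is 2 tissues × 3 treatments with 13 animals
  per tissue.

## Worked example

```r
library(isodecodeR)

sim    <- simulateAnnotation(n_anticodons = 12, dup_fraction = 0.4, seed = 42)
genes  <- sim$genes
groups <- collapseIdenticalSequences(genes)
groups
#> SequenceGroups with 45 unique-sequence groups
#>   member loci: 55 | multicopy groups: 7 | largest group: 3

sc <- simulateCounts(groups, seed = 43, phi = 0.1,
                     spike = data.frame(group_id = groupIds(groups)[3],
                                        tissue = "muscle",
                                        treatment = "ART-LOS", fc = 6))
cd     <- SummarizedExperiment::colData(sc$counts)
muscle <- sc$counts[, cd$tissue == "muscle"]
roles  <- c(control = "Control-AI", normal = "ART-Normal", los = "ART-LOS")
res    <- deTest(muscle, roles, c("control", "los"), groups = groups)
res[res$called, c("group_id", "anticodon", "log2_fold_change",
                  "p_value", "fdr", "direction")]
#>   group_id anticodon log2_fold_change      p_value          fdr direction
#> 3   SG0003       UUU          2.68964 3.266387e-20 1.469874e-18        up
```

Of the 55 simulated loci only 45 distinct sequences exist; the one group
planted with a 6-fold increase in LOS muscle is the only call, at an
observed log2 fold change of 2.69 (planted: log2 6 ≈ 2.58). A
copy-number/expression correlation on the same data
(`copyNumberExpression()`) returns r = −0.18 (p = 0.58, n = 12): the
generator drew expression independently of copy number, and the analysis
reports exactly that.

The full pipeline over files on disk (GFF3 + FASTA + count TSV + sample
sheet, optional CDS/TPM and DMR BED) is driven by `runPipeline()` with a
`pipelineConfig()`; it writes all result TSVs plus a JSON manifest of
parameters, input checksums and warnings.

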