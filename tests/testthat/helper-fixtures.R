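# Shared fixtures, built in code at test time.

rolesDefault <- c(control = "Control-AI", normal = "ART-Normal",
                  los = "ART-LOS")

# A hand-built TrnaGeneSet: 6 loci, two sharing a sequence.
toyGenes <- function() {
  seqs <- c(
    g1 = paste(rep("GGCUCAGUU", 8), collapse = ""),   # Gly-GCC
    g2 = paste(rep("GGCUCAGUU", 8), collapse = ""),   # identical to g1
    g3 = paste(rep("CCGGAUAGC", 8), collapse = ""),   # Gly-GCC variant
    g4 = paste(rep("AAGGCUUCA", 8), collapse = ""),   # Pro-UGG
    g5 = paste(rep("UUCGAAGGC", 8), collapse = ""),   # Pro-UGG variant
    g6 = paste(rep("CAUGCAUGC", 8), collapse = ""))   # Met-CAU
  aa <- c("Gly", "Gly", "Gly", "Pro", "Pro", "Met")
  ac <- c("GCC", "GCC", "GCC", "UGG", "UGG", "CAU")
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2", "chr2", "chr3", "MT"),
    IRanges::IRanges(start = seq(1000, by = 5000, length.out = 6),
                     width = nchar(seqs)),
    strand = c("+", "-", "+", "+", "-", "+"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = names(seqs), amino_acid = aa, anticodon = ac,
    compartment = c(rep("nuclear", 5), "mito"),
    mature_sequence = unname(seqs), confidence = "high")
  TrnaGeneSet(gr)
}

# Small raw TrnaCounts over an explicit design.
toyCounts <- function(mat, tissue, treatment, individual = NULL) {
  if (is.null(individual)) individual <- colnames(mat)
  cd <- S4Vectors::DataFrame(tissue = tissue, treatment = treatment,
                             individual = individual,
                             row.names = colnames(mat))
  TrnaCounts(mat, cd, scale = "raw")
}

# Builds a complete synthetic study on disk and returns its pipeline
# configuration.
buildStudy <- function(dir, seed = 501) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateAnnotation(n_anticodons = 15, dup_fraction = 0.4,
                            seed = seed)
  groups <- collapseIdenticalSequences(sim$genes)
  writeAnnotationFiles(sim$genes, file.path(dir, "ann.gff3"),
                       file.path(dir, "genome.fa"))
  sc <- simulateCounts(groups, seed = seed + 1, phi = 0.1)
  mat <- SummarizedExperiment::assay(sc$counts)
  write.table(data.frame(group_id = rownames(mat), mat,
                         check.names = FALSE),
              file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cd <- SummarizedExperiment::colData(sc$counts)
  write.table(data.frame(sample_id = rownames(cd), tissue = cd$tissue,
                         treatment = cd$treatment,
                         individual = cd$individual),
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  scds <- simulateCds(n_genes = 50, seed = seed + 2)
  Biostrings::writeXStringSet(scds$cds, file.path(dir, "cds.fa"))
  write.table(data.frame(gene_id = rownames(scds$tpm), scds$tpm,
                         check.names = FALSE),
              file.path(dir, "tpm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(scds$meta, file.path(dir, "tpm_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sdm <- simulateDmrs(sim$genes, c(0L, 3000L, 5000L), seed = seed + 3)
  writeBed(sdm$dmrs, file.path(dir, "dmrs.bed"))
  pipelineConfig(
    annotation_gff = file.path(dir, "ann.gff3"),
    genome_fasta = file.path(dir, "genome.fa"),
    counts_tsv = file.path(dir, "counts.tsv"),
    sample_sheet_tsv = file.path(dir, "samples.tsv"),
    cds_fasta = file.path(dir, "cds.fa"),
    tpm_tsv = file.path(dir, "tpm.tsv"),
    tpm_sample_sheet_tsv = file.path(dir, "tpm_samples.tsv"),
    dmr_bed = file.path(dir, "dmrs.bed"),
    seed = seed, outdir = file.path(dir, "out"))
}

# Brute-force Benjamini-Hochberg, straight from the step-up definition.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (k in n:1) {
    val <- min(prev, n * p[o[k]] / k)
    adj[o[k]] <- min(1, val)
    prev <- val
  }
  adj
}

# Sense-codon helpers used across codon-usage tests.
codons61 <- function() {
  tab <- buildCodonTable()
  tab$codon[!tab$is_stop]
}

senseTable61 <- function() {
  tab <- buildCodonTable()
  tab[!tab$is_stop, ]
}
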