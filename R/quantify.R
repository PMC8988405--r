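#' Read a count matrix and sample sheet
#'
#' @param counts Path to a TSV whose first column is the feature id and
#'   whose header names samples, or a ready numeric matrix.
#' @param sample_sheet Path to a TSV with columns `sample_id`, `tissue`,
#'   `treatment`, `individual`, or a `data.frame`.
#' @return A [TrnaCounts-class] with `scale = "raw"`; sample order follows
#'   the sample sheet.
#' @export
readCounts <- function(counts, sample_sheet) {
  if (is.character(counts)) {
    df <- utils::read.delim(counts, check.names = FALSE,
                            stringsAsFactors = FALSE)
    mat <- as.matrix(df[, -1L, drop = FALSE])
    rownames(mat) <- df[[1L]]
  } else mat <- as.matrix(counts)
  if (is.character(sample_sheet))
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  meta <- as.data.frame(sample_sheet)
  stopifnot(all(c("sample_id", "tissue", "treatment", "individual") %in%
                  colnames(meta)))
  absent <- setdiff(meta$sample_id, colnames(mat))
  extra <- setdiff(colnames(mat), meta$sample_id)
  if (length(absent) > 0L)
    stop("sample(s) in sheet missing from count matrix: ",
         paste(absent, collapse = ", "))
  if (length(extra) > 0L)
    stop("sample(s) in count matrix missing from sheet: ",
         paste(extra, collapse = ", "))
  if (any(is.na(mat)) || any(mat < 0) || any(mat != floor(mat)))
    stop("raw counts must be non-negative integers")
  mat <- mat[, meta$sample_id, drop = FALSE]
  storage.mode(mat) <- "integer"
  cd <- DataFrame(tissue = meta$tissue, treatment = meta$treatment,
                  individual = meta$individual,
                  row.names = meta$sample_id)
  TrnaCounts(mat, cd, scale = "raw")
}

#' Assign reads to unique-sequence groups by exact match
#'
#' Embodies the resolution of tRNA multi-mapping by sequence collapsing: a
#' read is first stripped of a terminal CCA (the post-transcriptional 3'
#' tail), then counted for the unique-sequence group it matches exactly,
#' provided its length is at least `min_len`. Because group sequences are
#' unique, no read can be assigned twice; non-matching or short reads are
#' tallied as unassigned.
#'
#' @param reads Character vector of reads (RNA or DNA alphabet).
#' @param groups A [SequenceGroups-class].
#' @param min_len Minimum retained read length (default 50).
#' @return Named integer vector of per-group counts with attribute
#'   `unassigned`.
#' @export
assignReads <- function(reads, groups, min_len = 50L) {
  reads <- chartr("acgtT", "ACGUU", reads)
  reads <- sub("CCA$", "", reads)
  seqs <- groupSequences(groups)
  idx <- match(reads, seqs)
  ok <- !is.na(idx) & nchar(reads) >= min_len
  counts <- tabulate(idx[ok], nbins = length(seqs))
  out <- stats::setNames(as.integer(counts), groupIds(groups))
  attr(out, "unassigned") <- length(reads) - sum(ok)
  out
}

#' Counts-per-million normalisation
#'
#' Scales each sample to a library of one million, optionally followed by
#' a `log2(CPM + 1)` transform. Columns with a zero library size are
#' returned as all zeros with a warning.
#'
#' @param x A [TrnaCounts-class] with `scale = "raw"`.
#' @param log2 Return `log2(CPM + 1)` instead of CPM.
#' @return A `TrnaCounts` with `scale` `"cpm"` or `"log2cpm"`.
#' @export
cpmNormalize <- function(x, log2 = FALSE) {
  stopifnot(countScale(x) == "raw")
  mat <- assay(x)
  lib <- colSums(mat)
  zero <- lib == 0
  if (any(zero)) {
    warning("zero library size in sample(s): ",
            paste(colnames(mat)[zero], collapse = ", "))
    lib[zero] <- 1
  }
  cpm <- sweep(mat, 2L, lib, "/") * 1e6
  if (log2) cpm <- log2(cpm + 1)
  TrnaCounts(cpm, colData(x), scale = if (log2) "log2cpm" else "cpm")
}

#' Flag features as expressed per tissue
#'
#' A feature is expressed in a tissue iff its raw count is positive in at
#' least `min_individuals` distinct individuals of that tissue (distinct
#' by the `individual` design column, so technical replicates cannot
#' satisfy the rule). An optional extra grouping column (e.g.
#' `"treatment"`) computes flags per treatment-within-tissue instead.
#'
#' @param x A raw [TrnaCounts-class].
#' @param min_individuals Minimum distinct expressing individuals
#'   (default 2).
#' @param within Optional additional `colData` column to stratify by.
#' @return Logical matrix features x groups (tissues, or
#'   `tissue.withinlevel` combinations).
#' @export
filterExpressed <- function(x, min_individuals = 2L, within = NULL) {
  stopifnot(countScale(x) == "raw")
  mat <- assay(x)
  cd <- colData(x)
  grp <- as.character(cd$tissue)
  if (!is.null(within))
    grp <- paste(grp, as.character(cd[[within]]), sep = ".")
  levels <- unique(grp)
  out <- matrix(FALSE, nrow(mat), length(levels),
                dimnames = list(rownames(mat), levels))
  for (g in levels) {
    cols <- which(grp == g)
    inds <- as.character(cd$individual[cols])
    if (length(unique(inds)) < min_individuals)
      warning("group ", g, " has fewer than ", min_individuals,
              " individuals")
    nz <- mat[, cols, drop = FALSE] > 0
    n_ind <- apply(nz, 1L, function(r) length(unique(inds[r])))
    out[, g] <- n_ind >= min_individuals
  }
  out
}

#' Aggregate counts to a coarser feature level
#'
#' Sums counts over features mapped to the same key (e.g. gene to
#' sequence group, or group to anticodon); column sums are preserved.
#'
#' @param x A raw [TrnaCounts-class].
#' @param mapping Named character vector: feature id -> key.
#' @return A raw `TrnaCounts` over the mapped keys.
#' @export
aggregateCounts <- function(x, mapping) {
  stopifnot(countScale(x) == "raw")
  mat <- assay(x)
  unmapped <- setdiff(rownames(mat), names(mapping))
  if (length(unmapped) > 0L)
    stop("feature(s) missing from mapping: ",
         paste(unmapped, collapse = ", "))
  key <- factor(mapping[rownames(mat)],
                levels = unique(unname(mapping[rownames(mat)])))
  agg <- rowsum(mat, key, reorder = FALSE)
  storage.mode(agg) <- "integer"
  TrnaCounts(agg, colData(x), scale = "raw")
}

#' Propagate sequence-group expression flags to member loci
#'
#' Loci with identical sequences are not individually resolvable, so a
#' locus is flagged expressed iff its sequence group is.
#'
#' @param group_flags Logical matrix groups x tissues from
#'   [filterExpressed()] on group-level counts.
#' @param groups A [SequenceGroups-class].
#' @return Logical matrix genes x tissues.
#' @export
geneFlagsFromGroups <- function(group_flags, groups) {
  g2g <- geneToGroup(groups)
  out <- group_flags[g2g, , drop = FALSE]
  rownames(out) <- names(g2g)
  out
}

#' Proportion of isodecoder gene copies expressed
#'
#' For each anticodon and tissue, the number of expressed gene copies
#' divided by the total annotated copies bearing that anticodon.
#' Anticodons with zero annotated copies are omitted.
#'
#' @param gene_flags Logical matrix genes x tissues (gene-level flags,
#'   typically via [geneFlagsFromGroups()]).
#' @param genes A [TrnaGeneSet-class] covering the flagged genes.
#' @return A `data.frame` (anticodon, tissue, expressed_copies,
#'   total_copies, fraction).
#' @export
isodecoderExpressedProportion <- function(gene_flags, genes) {
  keys <- stats::setNames(anticodonKeys(genes), geneIds(genes))
  flagged <- intersect(rownames(gene_flags), names(keys))
  stopifnot(length(flagged) > 0L)
  totals <- table(keys)
  rows <- list()
  for (tis in colnames(gene_flags)) {
    expr_genes <- flagged[gene_flags[flagged, tis]]
    expressed <- table(factor(keys[expr_genes], levels = names(totals)))
    rows[[tis]] <- data.frame(
      anticodon = names(totals), tissue = tis,
      expressed_copies = as.integer(expressed),
      total_copies = as.integer(totals),
      fraction = as.integer(expressed) / as.integer(totals),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}
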