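#' Pearson correlation with t-distribution p-value
#'
#' Standard product-moment correlation; the two-sided p-value follows a
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r`, `p_value` and `n`.
#' @export
pearsonCor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Correlation of tRNA expression with gene copy number
#'
#' Pearson correlation between per-anticodon expression (mean CPM) and
#' annotated gene copy number over matched anticodon keys. A `drop` list
#' removes anticodons (e.g. very-high-copy families) before computing, as
#' a sensitivity analysis.
#'
#' @param expression Named numeric vector of per-anticodon mean CPM.
#' @param copy_table Named integer vector from [copyNumber()] at
#'   anticodon level.
#' @param drop Optional anticodon keys to exclude.
#' @param log2 Correlate on `log2(CPM + 1)` instead of CPM.
#' @return List with `r`, `p_value` and `n`.
#' @export
copyNumberExpression <- function(expression, copy_table, drop = NULL,
                                 log2 = FALSE) {
  keys <- intersect(names(expression), names(copy_table))
  keys <- setdiff(keys, drop)
  if (length(keys) < 3L) stop("fewer than 3 matched anticodon keys")
  e <- as.numeric(expression[keys])
  if (log2) e <- log2(e + 1)
  pearsonCor(e, as.numeric(copy_table[keys]))
}

#' Percentages within amino-acid families
#'
#' Rescales non-negative per-codon or per-anticodon values so that each
#' amino-acid family sums to 100. Keys are either DNA codons, RNA
#' anticodon triplets, or `"AminoAcid-Anticodon"` labels; the family of a
#' bare anticodon is that of its Watson-Crick codon. Zero-sum families
#' become `NA`.
#'
#' @param values Named non-negative numeric vector.
#' @return Numeric vector of percentages, same names and order.
#' @export
familyPercentages <- function(values) {
  stopifnot(!is.null(names(values)), all(values >= 0, na.rm = TRUE))
  fam <- .familyOfKeys(names(values))
  out <- values
  for (f in unique(fam)) {
    idx <- which(fam == f)
    tot <- sum(values[idx], na.rm = TRUE)
    out[idx] <- if (tot == 0) NA_real_ else values[idx] * 100 / tot
  }
  out
}

.familyOfKeys <- function(keys) {
  sense <- .senseTable()
  aa_of_codon <- stats::setNames(sense$amino_acid, sense$codon)
  vapply(keys, function(k) {
    if (grepl("-", k, fixed = TRUE))
      return(strsplit(k, "-", fixed = TRUE)[[1]][1])
    if (grepl("^[ACGT]{3}$", k) && k %in% names(aa_of_codon))
      return(unname(aa_of_codon[k]))
    if (grepl("^[ACGU]{3}$", k)) {
      cd <- anticodonToCodon(k)
      if (cd %in% names(aa_of_codon)) return(unname(aa_of_codon[cd]))
    }
    stop("cannot determine amino-acid family of key: ", k)
  }, character(1))
}

#' Correlation of codon usage with tRNA expression
#'
#' Pairs family-percentage RSCU values (keyed by DNA codon) with
#' family-percentage anticodon expression through the Watson-Crick codon
#' of each anticodon; anticodons without an annotated gene are excluded
#' rather than zero-filled. Pearson correlation over all pairs across
#' families.
#'
#' @param usage_pct Named numeric vector, percentages per codon.
#' @param expr_pct Named numeric vector, percentages per anticodon
#'   (`"AminoAcid-Anticodon"` or bare RNA triplet keys).
#' @return List with `r`, `p_value` and `n`.
#' @export
rscuExpressionCorrelation <- function(usage_pct, expr_pct) {
  keys <- names(expr_pct)
  ac <- ifelse(grepl("-", keys, fixed = TRUE),
               vapply(strsplit(keys, "-", fixed = TRUE), `[`,
                      character(1), 2L),
               keys)
  codons <- anticodonToCodon(ac)
  hit <- codons %in% names(usage_pct)
  u <- as.numeric(usage_pct[codons[hit]])
  e <- as.numeric(expr_pct[hit])
  ok <- !is.na(u) & !is.na(e)
  if (sum(ok) < 3L) stop("fewer than 3 codon/anticodon pairs")
  pearsonCor(u[ok], e[ok])
}

#' Shared and unique membership partition across conditions
#'
#' Counts every non-empty membership pattern of 2 or 3 condition sets
#' (the regions of a Venn diagram) with percentages over the union.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return `data.frame` (region, count, percent); regions are labelled
#'   by the conditions an element belongs to, joined by `&`.
#' @export
sharedUnique <- function(sets) {
  stopifnot(length(sets) %in% c(2L, 3L), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  if (length(all_ids) == 0L) stop("empty union")
  membership <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  labels <- unlist(lapply(seq_along(sets), function(k) {
    combn(names(sets), k, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = labels))
  data.frame(region = labels,
             count = as.integer(counts),
             percent = as.integer(counts) * 100 / length(all_ids),
             stringsAsFactors = FALSE)
}

#' Per-anticodon mean CPM for a sample subset
#'
#' Helper producing the expression vector used by the correlation
#' analyses: aggregate raw counts to anticodon level, CPM-normalise, and
#' average over the selected samples.
#'
#' @param x A raw [TrnaCounts-class] at sequence-group level.
#' @param groups A [SequenceGroups-class] matching the features of `x`.
#' @param samples Sample ids to average over (default: all).
#' @return Named numeric vector keyed `"AminoAcid-Anticodon"`.
#' @export
anticodonMeanCpm <- function(x, groups, samples = colnames(x)) {
  info <- groupInfo(groups)
  mapping <- stats::setNames(paste(info$amino_acid, info$anticodon,
                                   sep = "-"), info$group_id)
  agg <- aggregateCounts(x, mapping)
  cpm <- assay(cpmNormalize(agg))
  rowMeans(cpm[, samples, drop = FALSE])
}
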