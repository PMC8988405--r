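#' The standard genetic code as a codon table
#'
#' @return A `data.frame` with columns `codon` (DNA triplet),
#'   `amino_acid` (three-letter code, `Stop` for stop codons) and
#'   `is_stop`; 61 sense codons over 20 amino acids plus the 3 stops.
#' @export
buildCodonTable <- function() {
  gc1 <- Biostrings::GENETIC_CODE
  aa3 <- Biostrings::AMINO_ACID_CODE
  codon <- names(gc1)
  is_stop <- gc1 == "*"
  amino_acid <- ifelse(is_stop, "Stop", unname(aa3[gc1]))
  data.frame(codon = codon, amino_acid = amino_acid,
             is_stop = unname(is_stop), stringsAsFactors = FALSE)
}

.senseTable <- function() {
  tab <- buildCodonTable()
  tab[!tab$is_stop, ]
}

.stopCodons <- function() {
  tab <- buildCodonTable()
  tab$codon[tab$is_stop]
}

#' Genes expressed per treatment-within-tissue group
#'
#' Applies the mRNA expressed-gene rule: a gene belongs to a group's
#' expressed set iff its TPM is at least `min_tpm` in at least `min_reps`
#' replicates of that tissue x treatment group (thresholds inclusive).
#'
#' @param tpm Numeric matrix of TPM values, genes x samples.
#' @param meta `data.frame` with columns `sample_id`, `tissue`,
#'   `treatment` covering the TPM columns.
#' @param min_tpm TPM threshold (default 1).
#' @param min_reps Minimum qualifying replicates (default 2).
#' @return Named list (`"tissue.treatment"`) of gene-id vectors.
#' @export
expressedGeneSet <- function(tpm, meta, min_tpm = 1, min_reps = 2) {
  tpm <- as.matrix(tpm)
  stopifnot(all(meta$sample_id %in% colnames(tpm)))
  key <- paste(meta$tissue, meta$treatment, sep = ".")
  out <- list()
  for (k in unique(key)) {
    smp <- meta$sample_id[key == k]
    if (length(smp) < min_reps) {
      warning("group ", k, " has fewer than ", min_reps,
              " replicates; empty expressed set")
      out[[k]] <- character()
      next
    }
    hits <- rowSums(tpm[, smp, drop = FALSE] >= min_tpm)
    out[[k]] <- rownames(tpm)[hits >= min_reps]
  }
  out
}

#' Codon frequencies of a CDS set
#'
#' Counts codon occurrences per gene (or pooled over genes) in frame from
#' position 1. The terminal stop codon is excluded from counting; internal
#' stop codons are counted but flagged in the QC report. Codons containing
#' ambiguity letters are skipped; sequences whose length is not divisible
#' by 3 are skipped entirely with a warning.
#'
#' @param cds A `DNAStringSet` (or FASTA path) of coding sequences.
#' @param scope `"per_gene"` (matrix genes x 64) or `"pooled"` (named
#'   vector of 64).
#' @return List with `counts`, and `qc` (`data.frame` of `gene`, `issue`
#'   in `skipped_length` / `internal_stop`).
#' @export
codonFrequencies <- function(cds, scope = c("per_gene", "pooled")) {
  scope <- match.arg(scope)
  if (is.character(cds)) cds <- Biostrings::readDNAStringSet(cds)
  if (length(cds) > 0L && is.null(names(cds)))
    names(cds) <- paste0("gene", seq_along(cds))
  stops <- .stopCodons()
  qc <- list()
  w <- Biostrings::width(cds)
  bad_len <- w %% 3L != 0L
  if (any(bad_len)) {
    warning(sum(bad_len), " CDS with length not divisible by 3 skipped")
    qc[["len"]] <- data.frame(gene = names(cds)[bad_len],
                              issue = "skipped_length")
    cds <- cds[!bad_len]; w <- w[!bad_len]
  }
  if (length(cds) == 0L) {
    counts0 <- stats::setNames(integer(64L), buildCodonTable()$codon)
    counts <- if (scope == "pooled") counts0 else
      matrix(integer(0), 0, 64, dimnames = list(NULL, names(counts0)))
    return(list(counts = counts, qc = .bindQc(qc)))
  }
  # drop a terminal stop before counting
  last <- as.character(Biostrings::subseq(cds, start = w - 2L, end = w))
  has_stop <- last %in% stops
  body <- cds
  if (any(has_stop & w == 3L)) {
    keep_w <- ifelse(has_stop, pmax(w - 3L, 0L), w)
  } else keep_w <- ifelse(has_stop, w - 3L, w)
  body <- Biostrings::subseq(cds, start = 1L,
                             end = keep_w)
  mat <- Biostrings::oligonucleotideFrequency(body, width = 3L, step = 3L)
  rownames(mat) <- names(cds)
  internal <- rowSums(mat[, stops, drop = FALSE]) > 0
  if (any(internal))
    qc[["stop"]] <- data.frame(gene = names(cds)[internal],
                               issue = "internal_stop")
  counts <- if (scope == "pooled") {
    pooled <- colSums(mat)
    stats::setNames(as.integer(pooled), names(pooled))
  } else mat
  list(counts = counts, qc = .bindQc(qc))
}

.bindQc <- function(qc) {
  if (length(qc) == 0L)
    return(data.frame(gene = character(), issue = character()))
  do.call(rbind, unname(qc))
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the family-uniform
#' expectation (family total / family size), so an unbiased family has
#' RSCU 1 for every member and RSCU values within a family sum to the
#' family size. Stop codons are excluded; families with zero total get
#' `NA`.
#'
#' @param counts Named codon-count vector (64 or 61 keys) or a per-gene
#'   matrix with codon columns.
#' @return Same shape as `counts`, restricted to the 61 sense codons.
#' @export
rscuValues <- function(counts) {
  .familyTransform(counts, function(v) {
    tot <- sum(v)
    if (tot == 0) rep(NA_real_, length(v)) else v / (tot / length(v))
  })
}

#' Relative adaptiveness of a codon (RAC)
#'
#' RAC is the codon count divided by the maximum count within its
#' synonymous family, so the most used codon of a family scores 1 and
#' values lie in \[0, 1\]. Families with zero total get `NA`.
#'
#' @inheritParams rscuValues
#' @return Same shape as `counts`, restricted to the 61 sense codons.
#' @export
racValues <- function(counts) {
  .familyTransform(counts, function(v) {
    mx <- max(v)
    if (mx == 0) rep(NA_real_, length(v)) else v / mx
  })
}

.familyTransform <- function(counts, f) {
  sense <- .senseTable()
  fam <- split(sense$codon, sense$amino_acid)
  one <- function(v) {
    v <- v[sense$codon]
    v[is.na(v)] <- 0
    names(v) <- sense$codon
    out <- stats::setNames(rep(NA_real_, length(v)), sense$codon)
    for (codons in fam) out[codons] <- f(as.numeric(v[codons]))
    out
  }
  if (is.matrix(counts)) {
    res <- t(apply(counts, 1L, one))
    colnames(res) <- sense$codon
    res
  } else one(counts)
}

#' Average per-gene usage profiles
#'
#' Unweighted arithmetic mean of per-gene RSCU (or RAC) values across
#' genes. Genes in which a family is entirely absent contribute `NA` for
#' that family and are excluded from its average rather than counted as
#' zero.
#'
#' @param profiles Matrix genes x sense codons of per-gene values.
#' @return Named numeric vector over the 61 sense codons.
#' @export
averagePerGene <- function(profiles) {
  stopifnot(is.matrix(profiles))
  colMeans(profiles, na.rm = TRUE)
}

#' Watson-Crick codon of an anticodon
#'
#' The anticodon (RNA, 5'->3') pairs antiparallel with its codon; the
#' Watson-Crick codon is therefore the reverse complement, written in the
#' DNA alphabet.
#'
#' @param anticodon RNA triplet(s) over A/C/G/U.
#' @return DNA codon triplet(s).
#' @export
anticodonToCodon <- function(anticodon) {
  vapply(anticodon, function(ac) {
    if (!grepl("^[ACGU]{3}$", ac))
      stop("invalid anticodon: ", ac)
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chartr("U", "T", ac))))
  }, character(1), USE.NAMES = !is.null(names(anticodon)))
}

#' Codon of an anticodon, and the reverse mapping
#'
#' @param codon DNA triplet(s).
#' @return RNA anticodon triplet(s).
#' @export
codonToAnticodon <- function(codon) {
  vapply(codon, function(cd) {
    chartr("T", "U", as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cd))))
  }, character(1), USE.NAMES = !is.null(names(codon)))
}

#' Codons decodable by an anticodon under wobble rules
#'
#' Codon positions 1-2 pair Watson-Crick with anticodon positions 36-35;
#' codon position 3 pairs with the wobble base (anticodon position 34, the
#' first base 5'->3') under the rule table G34 -> C/U, U34 -> A/G,
#' C34 -> G, and A34 -> U, extended to U/C/A when A34 is read as inosine.
#'
#' @param anticodon RNA triplet 5'->3'.
#' @param inosine_at_A34 Treat A34 as inosine (default `TRUE`).
#' @return Character vector of decodable DNA codons.
#' @export
wobbleDecodes <- function(anticodon, inosine_at_A34 = TRUE) {
  if (!grepl("^[ACGU]{3}$", anticodon))
    stop("invalid anticodon: ", anticodon)
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  b <- strsplit(anticodon, "")[[1]]
  first2 <- paste0(wc[b[3]], wc[b[2]])
  third <- switch(b[1],
    G = c("C", "T"),
    U = c("A", "G"),
    C = "G",
    A = if (inosine_at_A34) c("T", "C", "A") else "T")
  paste0(first2, third)
}

#' Preferred synonymous codon per amino-acid family
#'
#' The codon with the highest count within each family; ties broken
#' lexicographically so the result is deterministic. Families with zero
#' total are reported as `NA`.
#'
#' @param counts Named codon-count vector.
#' @return Named character vector, one codon per amino-acid family.
#' @export
preferredCodons <- function(counts) {
  sense <- .senseTable()
  fam <- split(sense$codon, sense$amino_acid)
  out <- vapply(fam, function(codons) {
    v <- as.numeric(counts[codons])
    v[is.na(v)] <- 0
    if (sum(v) == 0) return(NA_character_)
    codons <- sort(codons)
    v <- as.numeric(counts[codons]); v[is.na(v)] <- 0
    codons[which.max(v)]
  }, character(1))
  out
}

#' Anticodon-codon concordance per amino-acid family
#'
#' For each amino-acid family, compares the Watson-Crick codon of the most
#' highly expressed anticodon against the most frequent codon of the
#' family. Families with no expressed anticodon are excluded from the
#' concordance denominator and listed separately.
#'
#' @param anticodon_expression Named numeric vector of expression values
#'   keyed `"AminoAcid-Anticodon"` (e.g. `"Pro-GGG"`).
#' @param counts Named codon-count vector for the matching group.
#' @return A `data.frame` (family, top_anticodon, top_codon, wc_codon,
#'   concordant) with attributes `n_concordant`, `n_families` and
#'   `unexpressed_families`.
#' @export
concordance <- function(anticodon_expression, counts) {
  keys <- names(anticodon_expression)
  stopifnot(!is.null(keys))
  parts <- strsplit(keys, "-", fixed = TRUE)
  fam_of <- vapply(parts, `[`, character(1), 1L)
  ac_of <- vapply(parts, `[`, character(1), 2L)
  pref <- preferredCodons(counts)
  families <- sort(unique(.senseTable()$amino_acid))
  rows <- list()
  unexpressed <- character()
  for (f in families) {
    in_f <- fam_of == f & !is.na(anticodon_expression) &
      anticodon_expression > 0
    if (!any(in_f)) { unexpressed <- c(unexpressed, f); next }
    vals <- anticodon_expression[in_f]
    acs <- ac_of[in_f]
    o <- order(-vals, acs)
    top_ac <- acs[o[1L]]
    wc <- anticodonToCodon(top_ac)
    top_cd <- pref[[f]]
    rows[[f]] <- data.frame(
      family = f, top_anticodon = top_ac, top_codon = top_cd,
      wc_codon = unname(wc),
      concordant = !is.na(top_cd) && wc == top_cd,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(family = character(), top_anticodon = character(),
               top_codon = character(), wc_codon = character(),
               concordant = logical())
  attr(out, "n_concordant") <- sum(out$concordant)
  attr(out, "n_families") <- nrow(out)
  attr(out, "unexpressed_families") <- unexpressed
  out
}
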