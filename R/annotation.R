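#' Parse a tRNAscan-SE / GtRNAdb style tRNA annotation
#'
#' Reads tRNA gene features from a GFF3 annotation and (optionally)
#' extracts their mature sequences from a genome or per-gene FASTA. Amino
#' acid and anticodon are taken from the GtRNAdb-style identifier token
#' `tRNA-<AA>-<anticodon>-<n>-<m>` when present, with explicit
#' `amino_acid` / `anticodon` attributes as fallback; they are annotation
#' attributes, never inferred from the sequence. Minus-strand genes are
#' reverse-complemented and exon-gap (intron) segments removed; DNA is
#' transliterated to the RNA alphabet. The post-transcriptional 3' CCA is
#' not part of the mature sequence.
#'
#' @param gff Path to a GFF3 file, or a `GRanges` as returned by
#'   [rtracklayer::import()].
#' @param sequences A genome `DNAStringSet` (names = contigs), a per-gene
#'   `DNAStringSet` (names = gene ids), a FASTA path, or `NULL` to skip
#'   sequence extraction.
#' @param mito_contig Name of the mitochondrial contig; genes on it get
#'   `compartment = "mito"`.
#' @param high_confidence_only Drop pseudogene / secondary-filtered
#'   records.
#' @return A [TrnaGeneSet-class].
#' @export
parseTrnaAnnotation <- function(gff, sequences = NULL, mito_contig = "MT",
                                high_confidence_only = FALSE) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3")
        else gff
  m <- mcols(gr)
  type <- tolower(as.character(m$type))
  trna <- gr[type %in% c("trna", "trna_gene", "pseudogene_trna")]
  exons <- gr[type == "exon"]
  if (length(trna) == 0L) return(.emptyTrnaGeneSet())

  tm <- mcols(trna)
  ids <- .firstNonEmpty(tm, c("ID", "Name", "gene_id"), length(trna))
  blank <- !nzchar(ids)
  if (any(blank)) ids[blank] <- paste0("trna_", which(blank))

  # amino acid + anticodon from the id token, else explicit attributes
  tok <- regmatches(ids, regexec(
    "tRNA-([A-Za-z]{3,4})-([ACGTUacgtu]{3})", ids))
  aa <- vapply(tok, function(t) if (length(t) == 3L) t[2] else NA_character_,
               character(1))
  ac <- vapply(tok, function(t) if (length(t) == 3L) t[3] else NA_character_,
               character(1))
  if ("amino_acid" %in% colnames(tm))
    aa <- ifelse(is.na(aa), as.character(tm$amino_acid), aa)
  if ("anticodon" %in% colnames(tm))
    ac <- ifelse(is.na(ac), as.character(tm$anticodon), ac)
  ac <- chartr("acgtuT", "ACGUUU", ac)
  bad <- is.na(aa) | is.na(ac) | !grepl("^[ACGU]{3}$", ac) |
    !aa %in% .AA_LABELS
  if (any(bad)) {
    warning(sum(bad), " tRNA record(s) with unparsable amino-acid/",
            "anticodon attributes were skipped")
    trna <- trna[!bad]; ids <- ids[!bad]; aa <- aa[!bad]; ac <- ac[!bad]
    tm <- mcols(trna)
    if (length(trna) == 0L) return(.emptyTrnaGeneSet())
  }

  conf <- .firstNonEmpty(tm, c("confidence"), length(trna))
  conf[!nzchar(conf)] <- "high"
  pseudo_hint <- grepl("pseudo", ids, ignore.case = TRUE)
  conf[conf == "high" & pseudo_hint] <- "pseudo"
  conf[!conf %in% c("high", "pseudo", "secondary_filtered")] <- "high"

  seqs <- .extractMatureSequences(trna, ids, exons, sequences)

  out <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(trna)),
    ranges = IRanges::IRanges(GenomicRanges::start(trna),
                              GenomicRanges::end(trna)),
    strand = GenomicRanges::strand(trna))
  mcols(out) <- DataFrame(
    gene_id = ids, amino_acid = aa, anticodon = ac,
    compartment = ifelse(as.character(GenomicRanges::seqnames(trna)) ==
                           mito_contig, "mito", "nuclear"),
    mature_sequence = seqs, confidence = conf)
  res <- TrnaGeneSet(out)
  if (high_confidence_only) res <- res[confidenceClass(res) == "high"]
  res
}

.emptyTrnaGeneSet <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr) <- DataFrame(gene_id = character(), amino_acid = character(),
                         anticodon = character(), compartment = character(),
                         mature_sequence = character(),
                         confidence = character())
  TrnaGeneSet(gr)
}

.firstNonEmpty <- function(m, cols, n) {
  out <- rep("", n)
  for (cl in cols) {
    if (cl %in% colnames(m)) {
      v <- as.character(m[[cl]])
      v[is.na(v)] <- ""
      out <- ifelse(nzchar(out), out, v)
    }
  }
  out
}

.extractMatureSequences <- function(trna, ids, exons, sequences) {
  if (is.null(sequences)) return(rep("", length(trna)))
  if (is.character(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  seq_names <- names(sequences)
  contigs <- as.character(GenomicRanges::seqnames(trna))
  genome_mode <- all(contigs %in% seq_names)
  if (!genome_mode) {
    if (all(ids %in% seq_names)) {
      s <- as.character(sequences[ids])
      return(chartr("acgtT", "ACGUU", s))
    }
    missing_ctg <- setdiff(unique(contigs), seq_names)
    stop("sequence source does not cover contig(s): ",
         paste(missing_ctg, collapse = ", "))
  }
  parent <- as.character(mcols(exons)$Parent)
  out <- character(length(trna))
  for (i in seq_along(trna)) {
    g <- trna[i]
    ex <- exons[parent == as.character(mcols(g)$ID %||% ids[i])]
    if (length(ex) == 0L) ex <- g
    ex <- ex[order(GenomicRanges::start(ex))]
    chrom <- contigs[i]
    pieces <- vapply(seq_along(ex), function(j) {
      as.character(Biostrings::subseq(sequences[[chrom]],
                                      GenomicRanges::start(ex)[j],
                                      GenomicRanges::end(ex)[j]))
    }, character(1))
    s <- Biostrings::DNAString(paste(pieces, collapse = ""))
    if (as.character(GenomicRanges::strand(g)) == "-")
      s <- Biostrings::reverseComplement(s)
    out[i] <- chartr("T", "U", as.character(s))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Collapse identical-sequence tRNA loci into sequence groups
#'
#' Multicopy tRNA families contain loci with byte-identical mature
#' sequences whose reads cannot be attributed to a single locus. This
#' partitions the gene set by exact mature sequence; each resulting group
#' is the unit of downstream expression analysis. Groups are ordered
#' lexicographically by sequence and numbered `SG0001, SG0002, ...`.
#'
#' @param genes A [TrnaGeneSet-class] with non-empty mature sequences.
#' @return A [SequenceGroups-class].
#' @export
collapseIdenticalSequences <- function(genes) {
  seqs <- as.character(mcols(granges(genes))$mature_sequence)
  if (length(seqs) > 0L && any(!nzchar(seqs)))
    stop("all genes must have a non-empty mature_sequence")
  ids <- geneIds(genes)
  ac <- anticodons(genes)
  aa <- aminoAcids(genes)
  uniq <- sort(unique(seqs))
  idx <- split(seq_along(seqs), factor(seqs, levels = uniq))
  members <- lapply(idx, function(i) ids[i])
  g_ac <- vapply(idx, function(i) {
    u <- unique(ac[i])
    if (length(u) > 1L)
      stop("annotation inconsistency: identical sequence with conflicting ",
           "anticodons (", paste(ids[i], collapse = ", "), ")")
    u
  }, character(1))
  g_aa <- vapply(idx, function(i) {
    u <- unique(aa[i])
    if (length(u) > 1L)
      stop("annotation inconsistency: identical sequence with conflicting ",
           "amino acids (", paste(ids[i], collapse = ", "), ")")
    u
  }, character(1))
  info <- DataFrame(
    group_id = sprintf("SG%04d", seq_along(uniq)),
    sequence = uniq,
    anticodon = unname(g_ac),
    amino_acid = unname(g_aa),
    members = IRanges::CharacterList(unname(members)))
  new("SequenceGroups", info = info)
}

#' Copy-number table of tRNA genes
#'
#' Tallies annotated tRNA gene copies either per anticodon (keys
#' `"AminoAcid-Anticodon"`, e.g. `"Gly-GCC"`) or per distinct mature
#' sequence. Keys absent from the annotation are reported as zero only
#' when a key `universe` is supplied.
#'
#' @param genes A [TrnaGeneSet-class].
#' @param level `"anticodon"` or `"sequence"`.
#' @param universe Optional character vector of keys to zero-fill.
#' @param high_confidence_only Count only `confidence == "high"` loci.
#' @return Named integer vector of copy counts.
#' @export
copyNumber <- function(genes, level = c("anticodon", "sequence"),
                       universe = NULL, high_confidence_only = FALSE) {
  level <- match.arg(level)
  if (high_confidence_only) genes <- genes[confidenceClass(genes) == "high"]
  keys <- if (level == "anticodon") anticodonKeys(genes)
          else as.character(mcols(granges(genes))$mature_sequence)
  if (length(keys) == 0L && is.null(universe))
    return(stats::setNames(integer(0), character(0)))
  tab <- table(keys)
  counts <- stats::setNames(as.integer(tab), names(tab))
  if (!is.null(universe)) {
    out <- stats::setNames(integer(length(universe)), universe)
    hit <- intersect(names(counts), universe)
    out[hit] <- counts[hit]
    return(out)
  }
  counts[order(names(counts))]
}

#' The 61 anticodons complementary to sense codons
#'
#' Keys are `"AminoAcid-Anticodon"` with the amino acid taken from the
#' standard genetic code of the Watson-Crick codon.
#'
#' @return Character vector of 61 keys.
#' @export
senseAnticodons <- function() {
  tab <- buildCodonTable()
  sense <- tab[!tab$is_stop, ]
  ac <- vapply(sense$codon, function(cd) {
    chartr("T", "U", as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cd))))
  }, character(1))
  sort(paste(sense$amino_acid, ac, sep = "-"))
}

#' Anticodons with no high-confidence gene copy
#'
#' Reports which anticodons of a key universe (default: the 61 anticodons
#' complementary to sense codons) have zero high-confidence annotated
#' copies. Pseudogene and secondary-filtered loci do not count as copies.
#'
#' @param genes A [TrnaGeneSet-class].
#' @param universe Character vector of `"AminoAcid-Anticodon"` keys;
#'   defaults to [senseAnticodons()].
#' @return Sorted character vector of keys with zero copies.
#' @export
missingAnticodons <- function(genes, universe = senseAnticodons()) {
  counts <- copyNumber(genes, level = "anticodon", universe = universe,
                       high_confidence_only = TRUE)
  sort(names(counts)[counts == 0L])
}

#' Write / read the gene table as TSV
#'
#' Serialisation of a [TrnaGeneSet-class] as a plain TSV so that a parsed
#' annotation round-trips exactly.
#'
#' @param genes A `TrnaGeneSet`.
#' @param path Output TSV path.
#' @export
writeGeneTable <- function(genes, path) {
  gr <- granges(genes)
  df <- data.frame(
    gene_id = geneIds(genes),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    amino_acid = aminoAcids(genes),
    anticodon = anticodons(genes),
    compartment = compartments(genes),
    sequence = as.character(mcols(gr)$mature_sequence),
    confidence = confidenceClass(genes),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneTable
#' @return `readGeneTable` returns a [TrnaGeneSet-class].
#' @export
readGeneTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sequence = "character"))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  mcols(gr) <- DataFrame(gene_id = df$gene_id, amino_acid = df$amino_acid,
                         anticodon = df$anticodon,
                         compartment = df$compartment,
                         mature_sequence = df$sequence,
                         confidence = df$confidence)
  TrnaGeneSet(gr)
}

#' Write the sequence-group table as TSV
#'
#' @param groups A [SequenceGroups-class].
#' @param path Output TSV path.
#' @export
writeGroupTable <- function(groups, path) {
  info <- groupInfo(groups)
  df <- data.frame(
    group_id = info$group_id,
    sequence = info$sequence,
    anticodon = info$anticodon,
    amino_acid = info$amino_acid,
    member_gene_ids = vapply(info$members, paste, character(1),
                             collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
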