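#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges CharacterList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

# Valid amino-acid labels: the 20 standard three-letter codes plus the
# selenocysteine and initiator-methionine labels used by tRNAscan-SE, and
# "Und" for undetermined predictions.
.AA_LABELS <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val",
  "SeC", "iMet", "Und", "Sup"
)

#' TrnaGeneSet: a set of annotated tRNA loci
#'
#' Wraps a [GenomicRanges::GRanges] whose metadata columns describe one
#' annotated tRNA locus per range: `gene_id` (unique), `amino_acid`
#' (three-letter code; `SeC` and `iMet` allowed), `anticodon` (RNA triplet
#' written 5'->3'), `compartment` (`nuclear` or `mito`), `mature_sequence`
#' (RNA alphabet, introns removed, no 3' CCA) and `confidence` (`high`,
#' `pseudo` or `secondary_filtered`). Coordinates are 1-based inclusive as
#' in GFF3.
#'
#' @slot genes A `GRanges` with the metadata columns listed above.
#' @export
setClass("TrnaGeneSet", slots = c(genes = "GRanges"))

setValidity("TrnaGeneSet", function(object) {
  gr <- object@genes
  need <- c("gene_id", "amino_acid", "anticodon", "compartment",
            "mature_sequence", "confidence")
  missing_cols <- setdiff(need, colnames(mcols(gr)))
  if (length(missing_cols) > 0L)
    return(paste("missing metadata columns:",
                 paste(missing_cols, collapse = ", ")))
  if (length(gr) == 0L) return(TRUE)
  m <- mcols(gr)
  if (anyDuplicated(m$gene_id))
    return("gene_id values must be unique")
  if (!all(m$compartment %in% c("nuclear", "mito")))
    return("compartment must be 'nuclear' or 'mito'")
  if (!all(m$confidence %in% c("high", "pseudo", "secondary_filtered")))
    return("confidence must be high, pseudo or secondary_filtered")
  if (!all(grepl("^[ACGU]{3}$", m$anticodon)))
    return("anticodon must be an RNA triplet over A/C/G/U")
  seqs <- as.character(m$mature_sequence)
  if (any(nzchar(seqs) & grepl("[^ACGU]", seqs)))
    return("mature_sequence must be over the RNA alphabet A/C/G/U")
  TRUE
})

#' Construct a TrnaGeneSet
#'
#' @param genes A `GRanges` carrying the required metadata columns
#'   (`gene_id`, `amino_acid`, `anticodon`, `compartment`,
#'   `mature_sequence`, `confidence`).
#' @return A [TrnaGeneSet-class] object.
#' @export
TrnaGeneSet <- function(genes) {
  new("TrnaGeneSet", genes = genes)
}

#' @describeIn TrnaGeneSet-class number of loci
#' @param x,object A `TrnaGeneSet`.
#' @export
setMethod("length", "TrnaGeneSet", function(x) length(x@genes))

#' @describeIn TrnaGeneSet-class subset loci
#' @param i index
#' @export
setMethod("[", "TrnaGeneSet", function(x, i) {
  new("TrnaGeneSet", genes = x@genes[i])
})

setMethod("show", "TrnaGeneSet", function(object) {
  n <- length(object)
  cat("TrnaGeneSet with", n, "tRNA loci\n")
  if (n > 0L) {
    m <- mcols(object@genes)
    cat("  anticodons:", length(unique(paste(m$amino_acid, m$anticodon))),
        "| mito loci:", sum(m$compartment == "mito"),
        "| high confidence:", sum(m$confidence == "high"), "\n")
  }
})

#' @describeIn TrnaGeneSet-class underlying `GRanges`
#' @export
granges <- function(x) x@genes

#' @describeIn TrnaGeneSet-class gene identifiers
#' @export
geneIds <- function(x) mcols(x@genes)$gene_id

#' @describeIn TrnaGeneSet-class anticodons (RNA, 5'->3')
#' @export
anticodons <- function(x) mcols(x@genes)$anticodon

#' @describeIn TrnaGeneSet-class three-letter amino-acid labels
#' @export
aminoAcids <- function(x) mcols(x@genes)$amino_acid

#' @describeIn TrnaGeneSet-class genome compartment per locus
#' @export
compartments <- function(x) mcols(x@genes)$compartment

#' @describeIn TrnaGeneSet-class mature sequences as an `RNAStringSet`
#' @export
matureSequences <- function(x) {
  seqs <- as.character(mcols(x@genes)$mature_sequence)
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- geneIds(x)
  out
}

#' @describeIn TrnaGeneSet-class confidence class per locus
#' @export
confidenceClass <- function(x) mcols(x@genes)$confidence

#' @describeIn TrnaGeneSet-class `"AminoAcid-Anticodon"` key per locus
#' @export
anticodonKeys <- function(x) {
  paste(aminoAcids(x), anticodons(x), sep = "-")
}

#' SequenceGroups: equivalence classes of identical-sequence tRNA loci
#'
#' The unit at which tRNA expression is analysed when reads cannot be
#' attributed to individual loci of a multicopy family. Each group collects
#' every locus whose mature sequence is byte-identical; members therefore
#' share anticodon and amino acid. Groups partition the input gene set and
#' are ordered lexicographically by sequence.
#'
#' @slot info A `DataFrame` with columns `group_id`, `sequence`,
#'   `anticodon`, `amino_acid` and `members` (a `CharacterList` of member
#'   gene ids).
#' @export
setClass("SequenceGroups", slots = c(info = "DataFrame"))

setValidity("SequenceGroups", function(object) {
  df <- object@info
  need <- c("group_id", "sequence", "anticodon", "amino_acid", "members")
  if (!all(need %in% colnames(df)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (anyDuplicated(df$group_id)) return("group_id values must be unique")
  if (anyDuplicated(df$sequence)) return("group sequences must be unique")
  sizes <- lengths(df$members)
  if (any(sizes == 0L)) return("every group must have at least one member")
  if (anyDuplicated(unlist(df$members)))
    return("a gene id may belong to only one group")
  TRUE
})

setMethod("length", "SequenceGroups", function(x) nrow(x@info))

setMethod("show", "SequenceGroups", function(object) {
  n <- length(object)
  cat("SequenceGroups with", n, "unique-sequence groups\n")
  if (n > 0L) {
    sizes <- lengths(object@info$members)
    cat("  member loci:", sum(sizes),
        "| multicopy groups:", sum(sizes > 1L),
        "| largest group:", max(sizes), "\n")
  }
})

#' @describeIn SequenceGroups-class group identifiers
#' @param x A `SequenceGroups`.
#' @export
groupIds <- function(x) x@info$group_id

#' @describeIn SequenceGroups-class group mature sequences
#' @export
groupSequences <- function(x) x@info$sequence

#' @describeIn SequenceGroups-class member gene ids as a `CharacterList`
#' @export
groupMembers <- function(x) {
  out <- x@info$members
  names(out) <- x@info$group_id
  out
}

#' @describeIn SequenceGroups-class per-group `DataFrame`
#' @export
groupInfo <- function(x) x@info

#' @describeIn SequenceGroups-class map each gene id to its group id
#' @export
geneToGroup <- function(x) {
  members <- groupMembers(x)
  genes <- unlist(members, use.names = FALSE)
  stats::setNames(rep(names(members), lengths(members)), genes)
}

#' TrnaCounts: a tRNA count matrix with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `counts` holds non-negative values over features (gene, sequence-group
#' or anticodon level) by samples, and whose `colData` carries the study
#' design columns `tissue`, `treatment` and `individual`. The scale of the
#' assay (`raw`, `cpm` or `log2cpm`) is recorded in `metadata(x)$scale`;
#' raw values must be integers.
#'
#' @export
setClass("TrnaCounts", contains = "SummarizedExperiment")

setValidity("TrnaCounts", function(object) {
  cd <- colData(object)
  need <- c("tissue", "treatment", "individual")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    return("sample ids must be unique")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("raw", "cpm", "log2cpm"))
    return("metadata(x)$scale must be 'raw', 'cpm' or 'log2cpm'")
  a <- assay(object)
  if (any(is.na(a))) return("counts must not contain NA")
  if (any(a < 0)) return("counts must be non-negative")
  if (sc == "raw" && any(a != floor(a)))
    return("raw counts must be integers")
  TRUE
})

#' Construct a TrnaCounts object
#'
#' @param counts Numeric matrix, features x samples, with row and column
#'   names.
#' @param sampleData A `data.frame` or `DataFrame` with one row per sample
#'   (rownames = sample ids) and columns `tissue`, `treatment`,
#'   `individual`.
#' @param scale One of `"raw"`, `"cpm"`, `"log2cpm"`.
#' @return A [TrnaCounts-class] object.
#' @export
TrnaCounts <- function(counts, sampleData, scale = "raw") {
  counts <- as.matrix(counts)
  sampleData <- DataFrame(sampleData)
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), rownames(sampleData))) {
    if (!setequal(colnames(counts), rownames(sampleData)))
      stop("sample ids in counts and sampleData differ: ",
           paste(union(setdiff(colnames(counts), rownames(sampleData)),
                       setdiff(rownames(sampleData), colnames(counts))),
                 collapse = ", "))
    counts <- counts[, rownames(sampleData), drop = FALSE]
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = sampleData)
  metadata(se)$scale <- scale
  new("TrnaCounts", se)
}

#' @describeIn TrnaCounts-class the recorded scale of the assay
#' @param x A `TrnaCounts`.
#' @export
countScale <- function(x) metadata(x)$scale

setMethod("show", "TrnaCounts", function(object) {
  cat("TrnaCounts:", nrow(object), "features x", ncol(object),
      "samples [scale:", paste0(countScale(object), "]\n"))
  cd <- colData(object)
  cat("  tissues:", paste(unique(cd$tissue), collapse = ", "), "\n")
  cat("  treatments:", paste(unique(cd$treatment), collapse = ", "), "\n")
})
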