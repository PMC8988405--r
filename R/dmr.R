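#' Read DMR intervals from BED
#'
#' BED coordinates are 0-based half-open; they are converted to 1-based
#' inclusive on read (`start + 1`, `end`).
#'
#' @param path BED3+ file (chrom, start, end, optional name, optional
#'   score, optional strand; a `direction` of `gain`/`loss` may ride in
#'   column 5).
#' @return A `GRanges`, 1-based inclusive, with `name` (and `direction`
#'   when present) metadata columns.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(GenomicRanges::GRanges(name = character()))
  parts <- strsplit(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 3L)) stop("BED line ", which(nf < 3L)[1L],
                         " has fewer than 3 fields")
  chrom <- vapply(parts, `[`, character(1), 1L)
  bstart <- as.integer(vapply(parts, `[`, character(1), 2L))
  bend <- as.integer(vapply(parts, `[`, character(1), 3L))
  bad <- which(bend <= bstart)
  if (length(bad) > 0L)
    stop("BED line ", bad[1L], ": end (", bend[bad[1L]],
         ") must exceed start (", bstart[bad[1L]], ")")
  name <- vapply(seq_along(parts), function(i) {
    if (nf[i] >= 4L) parts[[i]][4L] else paste0("interval_", i)
  }, character(1))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(bstart + 1L, bend))
  mcols(gr)$name <- name
  if (all(nf >= 5L)) {
    col5 <- vapply(parts, `[`, character(1), 5L)
    if (all(col5 %in% c("gain", "loss"))) mcols(gr)$direction <- col5
  }
  gr
}

#' Write intervals as BED
#'
#' Inverse of [readBed()]: 1-based inclusive intervals are written as
#' 0-based half-open BED records.
#'
#' @param gr A `GRanges` with a `name` metadata column.
#' @param path Output path.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = mcols(gr)$name,
    stringsAsFactors = FALSE)
  if (!is.null(mcols(gr)$direction)) df$direction <- mcols(gr)$direction
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' tRNA genes within a window of DMRs
#'
#' Reports every (gene, DMR) pair whose distance is at most `window`
#' (inclusive). Overlapping pairs have distance 0 with relation
#' `overlap_gene_body` when the DMR intersects the gene span; otherwise
#' the distance is the gap between the nearest interval ends. Strand is
#' ignored. Each pair carries the number of loci sharing the gene's exact
#' sequence when `groups` is supplied, flagging pairs whose locus-level
#' expression attribution is masked by identical copies.
#'
#' @param genes A [TrnaGeneSet-class].
#' @param dmrs A `GRanges` of DMRs (1-based, e.g. from [readBed()]).
#' @param window Maximum distance in bp (default 5000, inclusive).
#' @param groups Optional [SequenceGroups-class] for the ambiguity count.
#' @return `data.frame` (gene_id, anticodon, dmr_name, distance,
#'   relation, identical_locus_count).
#' @export
genesNearDmrs <- function(genes, dmrs, window = 5000L, groups = NULL) {
  gr <- granges(genes)
  rows <- list()
  g_chrom <- as.character(GenomicRanges::seqnames(gr))
  g_start <- GenomicRanges::start(gr); g_end <- GenomicRanges::end(gr)
  d_chrom <- as.character(GenomicRanges::seqnames(dmrs))
  d_start <- GenomicRanges::start(dmrs); d_end <- GenomicRanges::end(dmrs)
  d_name <- mcols(dmrs)$name
  k <- 0L
  for (i in seq_along(gr)) {
    same <- which(d_chrom == g_chrom[i])
    for (j in same) {
      if (d_start[j] <= g_end[i] && d_end[j] >= g_start[i]) {
        dist <- 0L; rel <- "overlap_gene_body"
      } else if (d_start[j] > g_end[i]) {
        dist <- d_start[j] - g_end[i]; rel <- "downstream_window"
      } else {
        dist <- g_start[i] - d_end[j]; rel <- "upstream_window"
      }
      if (dist <= window) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          gene_id = geneIds(genes)[i],
          anticodon = anticodonKeys(genes)[i],
          dmr_name = d_name[j],
          distance = dist, relation = rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (k > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(), anticodon = character(),
               dmr_name = character(), distance = integer(),
               relation = character(), stringsAsFactors = FALSE)
  out$identical_locus_count <- if (is.null(groups))
    rep(NA_integer_, nrow(out)) else
    vapply(out$gene_id, ambiguityAnnotation, integer(1), groups = groups)
  rownames(out) <- NULL
  out
}

#' Identical-sequence ambiguity of a locus
#'
#' Number of loci (including the queried one) sharing the gene's exact
#' mature sequence, i.e. the size of its sequence group. A methylated
#' locus inside a large group cannot be attributed locus-level expression
#' changes.
#'
#' @param gene_id A gene id.
#' @param groups A [SequenceGroups-class].
#' @return Integer group size.
#' @export
ambiguityAnnotation <- function(gene_id, groups) {
  members <- groupMembers(groups)
  hit <- which(vapply(members, function(m) gene_id %in% m, logical(1)))
  if (length(hit) != 1L)
    stop("gene ", gene_id, " not found in exactly one sequence group")
  length(members[[hit]])
}
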