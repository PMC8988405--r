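# Seeded generators with recorded ground truth. Every generator is a pure
# function of its parameters and seed; the returned `truth` records what
# downstream stages must recover.

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

.randomRna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

#' Simulate a multicopy tRNA annotation
#'
#' Generates tRNA loci for `n_anticodons` randomly chosen anticodons, each
#' with a random number of copies; within an anticodon, a fraction
#' `dup_fraction` of the copies are exact sequence duplicates of one
#' template (emulating multicopy families whose reads cannot be told
#' apart), the remainder unique. Mature sequences are random 72-90 nt RNA,
#' unique across families. The last `n_mito` loci are placed on the
#' mitochondrial contig. A fraction of genes may carry an intron
#' (two-exon structure) to exercise exon concatenation.
#'
#' @param n_anticodons Number of distinct anticodons (default 20).
#' @param copies_range Integer range of copies per anticodon.
#' @param dup_fraction Fraction of copies that are exact duplicates.
#' @param seed Integer seed.
#' @param n_mito Number of mitochondrial loci (default 2).
#' @param mito_contig Mitochondrial contig name.
#' @param intron_fraction Fraction of genes given a 12 bp intron.
#' @param spacing Gap between consecutive loci on a contig (bp).
#' @return List with `genes` ([TrnaGeneSet-class]) and `truth` (seed,
#'   parameters, expected gene -> sequence map and group count).
#' @export
simulateAnnotation <- function(n_anticodons = 20L, copies_range = c(2L, 8L),
                               dup_fraction = 0.3, seed = 1L,
                               n_mito = 2L, mito_contig = "MT",
                               intron_fraction = 0, spacing = 1000L) {
  stopifnot(dup_fraction >= 0, dup_fraction <= 1)
  .withSeed(seed, {
    keys <- sample(senseAnticodons(), n_anticodons)
    used_seqs <- character()
    gene_rows <- list()
    for (key in keys) {
      parts <- strsplit(key, "-", fixed = TRUE)[[1]]
      aa <- parts[1L]; ac <- parts[2L]
      n_copies <- sample(copies_range[1L]:copies_range[2L], 1L)
      n_dup <- round(dup_fraction * n_copies)
      n_templates <- (n_copies - n_dup) + as.integer(n_dup > 0L)
      seqs <- character(n_templates)
      for (i in seq_len(n_templates)) {
        repeat {
          s <- .randomRna(sample(72:90, 1L))
          if (!s %in% used_seqs) break
        }
        seqs[i] <- s
        used_seqs <- c(used_seqs, s)
      }
      per_copy <- if (n_dup > 0L) c(rep(seqs[1L], n_dup), seqs[-1L])
                  else seqs
      for (i in seq_len(n_copies)) {
        gene_rows[[length(gene_rows) + 1L]] <- list(
          gene_id = sprintf("tRNA-%s-%s-%d-%d", aa, chartr("U", "T", ac),
                            match(key, keys), i),
          amino_acid = aa, anticodon = ac, sequence = per_copy[i])
      }
    }
    n <- length(gene_rows)
    ord <- sample(n)  # interleave families along the chromosomes
    gene_rows <- gene_rows[ord]
    chroms <- rep(paste0("chr", 1:4), length.out = n)
    if (n_mito > 0L) chroms[seq(n - n_mito + 1L, n)] <- mito_contig
    strands <- rep(c("+", "-"), length.out = n)
    has_intron <- stats::runif(n) < intron_fraction
    intron_len <- 12L
    starts <- integer(n); ends <- integer(n)
    pos <- stats::setNames(rep(1000L, length(unique(chroms))), unique(chroms))
    for (i in seq_len(n)) {
      len <- nchar(gene_rows[[i]]$sequence) +
        if (has_intron[i]) intron_len else 0L
      starts[i] <- pos[[chroms[i]]]
      ends[i] <- starts[i] + len - 1L
      pos[[chroms[i]]] <- ends[i] + spacing
    }
    gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, ends),
                                 strand = strands)
    mcols(gr) <- DataFrame(
      gene_id = vapply(gene_rows, `[[`, character(1), "gene_id"),
      amino_acid = vapply(gene_rows, `[[`, character(1), "amino_acid"),
      anticodon = vapply(gene_rows, `[[`, character(1), "anticodon"),
      compartment = ifelse(chroms == mito_contig, "mito", "nuclear"),
      mature_sequence = vapply(gene_rows, `[[`, character(1), "sequence"),
      confidence = "high",
      has_intron = has_intron)
    genes <- TrnaGeneSet(gr)
    seqs <- vapply(gene_rows, `[[`, character(1), "sequence")
    truth <- list(
      seed = seed, n_anticodons = n_anticodons,
      dup_fraction = dup_fraction,
      gene_sequence = stats::setNames(seqs, geneIds(genes)),
      n_groups = length(unique(seqs)),
      intron_length = intron_len,
      mito_contig = mito_contig)
    list(genes = genes, truth = truth)
  })
}

#' Write a simulated annotation as GFF3 + genome FASTA
#'
#' Emits the tRNAscan-SE-style GFF3 (with two exon children for intron
#' genes) and a genome FASTA in which each mature sequence is embedded at
#' its coordinates (reverse-complemented on the minus strand, intron
#' filler inserted), so that [parseTrnaAnnotation()] recovers the input.
#'
#' @param genes A [TrnaGeneSet-class] from [simulateAnnotation()].
#' @param gff_path,fasta_path Output paths.
#' @export
writeAnnotationFiles <- function(genes, gff_path, fasta_path) {
  gr <- granges(genes)
  m <- mcols(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  contig_len <- tapply(GenomicRanges::end(gr) + 100L, chroms, max)
  contigs <- lapply(contig_len, function(L)
    rep.int(charToRaw("A"), L))
  has_intron <- if ("has_intron" %in% colnames(m)) m$has_intron
                else rep(FALSE, length(gr))
  lines <- c("##gff-version 3")
  for (i in seq_along(gr)) {
    chrom <- chroms[i]
    st <- GenomicRanges::start(gr)[i]; en <- GenomicRanges::end(gr)[i]
    strand <- as.character(GenomicRanges::strand(gr))[i]
    mature <- m$mature_sequence[i]
    glen <- en - st + 1L
    mlen <- nchar(mature)
    if (has_intron[i]) {
      # exon1 = first 37 mature bases, intron, exon2 = rest
      e1 <- 37L
      intron <- glen - mlen
      genomic <- paste0(substr(mature, 1L, e1),
                        paste(rep("A", intron), collapse = ""),
                        substr(mature, e1 + 1L, mlen))
      ex <- rbind(c(st, st + e1 - 1L),
                  c(st + e1 + intron, en))
      if (strand == "-") {
        # reverse-complementing the whole span puts the 5' exon rightmost
        genomic <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(chartr("U", "T", genomic))))
        ex <- rbind(c(st, st + (mlen - e1) - 1L),
                    c(en - e1 + 1L, en))
      } else {
        genomic <- chartr("U", "T", genomic)
      }
    } else {
      genomic <- chartr("U", "T", mature)
      if (strand == "-")
        genomic <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(genomic)))
      ex <- NULL
    }
    raw <- charToRaw(genomic)
    contigs[[chrom]][st:en] <- raw
    id <- m$gene_id[i]
    lines <- c(lines, paste(chrom, "tRNAscan-SE", "tRNA", st, en, ".",
                            strand, ".",
                            paste0("ID=", id, ";confidence=",
                                   m$confidence[i]),
                            sep = "\t"))
    if (!is.null(ex)) {
      for (k in 1:2)
        lines <- c(lines, paste(chrom, "tRNAscan-SE", "exon",
                                ex[k, 1L], ex[k, 2L], ".", strand, ".",
                                paste0("ID=", id, ".exon", k,
                                       ";Parent=", id),
                                sep = "\t"))
    }
  }
  writeLines(lines, gff_path)
  fasta <- Biostrings::DNAStringSet(vapply(contigs, rawToChar, character(1)))
  names(fasta) <- names(contigs)
  Biostrings::writeXStringSet(fasta, fasta_path, width = 80L)
  invisible(list(gff = gff_path, fasta = fasta_path))
}

#' Simulate a tRNA-seq count matrix over a treatment x tissue design
#'
#' Negative-binomial counts at sequence-group level for a design of
#' `tissues` x `treatments` with `n_per_treatment` animals per treatment
#' (the same animals provide both tissues). Per-group baseline rates are
#' log-normal, optionally proportional to group copy number; spiked
#' groups are multiplied by their fold change in one tissue/treatment;
#' silenced groups have rate zero everywhere. Library sizes are
#' log-uniform over `lib_size_range`.
#'
#' @param groups A [SequenceGroups-class].
#' @param tissues,treatments Design labels.
#' @param n_per_treatment Animals per treatment (recycled over
#'   treatments).
#' @param lib_size_range Range of expected library sizes.
#' @param phi Negative-binomial dispersion (0 = Poisson).
#' @param spike `data.frame(group_id, tissue, treatment, fc)` of planted
#'   fold changes, or `NULL`.
#' @param silence Character vector of silenced group ids.
#' @param copy_relation `"independent"` or `"proportional"` (to group
#'   copy number).
#' @param seed Integer seed.
#' @return List with `counts` ([TrnaCounts-class]) and `truth`.
#' @export
simulateCounts <- function(groups,
                           tissues = c("muscle", "liver"),
                           treatments = c("Control-AI", "ART-Normal",
                                          "ART-LOS"),
                           n_per_treatment = c(5L, 4L, 4L),
                           lib_size_range = c(5e5, 2e6),
                           phi = 0.1, spike = NULL, silence = character(),
                           copy_relation = c("independent", "proportional"),
                           seed = 1L) {
  copy_relation <- match.arg(copy_relation)
  n_per_treatment <- rep_len(n_per_treatment, length(treatments))
  gids <- groupIds(groups)
  sizes <- lengths(groupMembers(groups))
  acs <- groupInfo(groups)$anticodon
  .withSeed(seed, {
    base <- if (copy_relation == "proportional") {
      sizes * stats::rlnorm(length(gids), 0, 0.1)
    } else {
      # independence must hold at anticodon level: draw one rate per
      # anticodon and split it over that anticodon's groups, so summed
      # expression does not scale with copy number
      ac_rate <- stats::setNames(
        stats::rlnorm(length(unique(acs)), log(100), 1), unique(acs))
      n_grp <- table(acs)
      ac_rate[acs] / as.numeric(n_grp[acs])
    }
    base[gids %in% silence] <- 0
    prop <- base / sum(base)
    animal <- paste0("F", sprintf("%02d", seq_len(sum(n_per_treatment))))
    animal_trt <- rep(treatments, n_per_treatment)
    meta <- do.call(rbind, lapply(tissues, function(tis) {
      data.frame(sample_id = paste(tis, animal, sep = "_"),
                 tissue = tis, treatment = animal_trt,
                 individual = animal, stringsAsFactors = FALSE)
    }))
    lib <- exp(stats::runif(nrow(meta), log(lib_size_range[1L]),
                            log(lib_size_range[2L])))
    mu <- matrix(prop, length(gids), nrow(meta)) %*% diag(lib)
    dimnames(mu) <- list(gids, meta$sample_id)
    if (!is.null(spike)) {
      for (r in seq_len(nrow(spike))) {
        cols <- meta$sample_id[meta$tissue == spike$tissue[r] &
                                 meta$treatment == spike$treatment[r]]
        mu[spike$group_id[r], cols] <- mu[spike$group_id[r], cols] *
          spike$fc[r]
      }
    }
    counts <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
    for (j in seq_len(ncol(mu))) {
      counts[, j] <- if (phi == 0) stats::rpois(nrow(mu), mu[, j])
        else stats::rnbinom(nrow(mu), size = 1 / phi, mu = mu[, j])
    }
    storage.mode(counts) <- "integer"
    cd <- DataFrame(tissue = meta$tissue, treatment = meta$treatment,
                    individual = meta$individual,
                    row.names = meta$sample_id)
    truth <- list(seed = seed, rates = prop, silenced = silence,
                  spike = spike, copy_relation = copy_relation,
                  lib_sizes = stats::setNames(lib, meta$sample_id),
                  expected_mu = mu, phi = phi, meta = meta)
    list(counts = TrnaCounts(counts, cd, scale = "raw"), truth = truth)
  })
}

#' Simulate a CDS set with controllable codon bias
#'
#' Generates `n_genes` coding sequences as `ATG` + weighted sense-codon
#' draws + a random stop, with lengths divisible by 3, plus a TPM matrix
#' marking all genes expressed. The truth records the exact codon draw
#' tally per gene (including the forced start codon).
#'
#' @param n_genes Number of genes.
#' @param codon_weights Named non-negative weights over the 61 sense
#'   codons (`NULL` = uniform).
#' @param length_range Range of body length in codons.
#' @param n_samples TPM matrix columns (default 2 replicates).
#' @param seed Integer seed.
#' @return List with `cds` (`DNAStringSet`), `tpm` (matrix), `meta`
#'   (sample sheet) and `truth` (per-gene codon tallies).
#' @export
simulateCds <- function(n_genes = 100L, codon_weights = NULL,
                        length_range = c(100L, 300L), n_samples = 2L,
                        seed = 1L) {
  sense <- .senseTable()$codon
  if (is.null(codon_weights))
    codon_weights <- stats::setNames(rep(1, length(sense)), sense)
  stopifnot(all(codon_weights >= 0), any(codon_weights > 0),
            all(names(codon_weights) %in% sense))
  w <- stats::setNames(numeric(length(sense)), sense)
  w[names(codon_weights)] <- codon_weights
  .withSeed(seed, {
    tallies <- matrix(0L, n_genes, 64L,
                      dimnames = list(paste0("g", sprintf("%03d",
                                                          seq_len(n_genes))),
                                      buildCodonTable()$codon))
    seqs <- character(n_genes)
    for (i in seq_len(n_genes)) {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      draws <- sample(sense, len, replace = TRUE, prob = w)
      stop_cd <- sample(.stopCodons(), 1L)
      seqs[i] <- paste0("ATG", paste(draws, collapse = ""), stop_cd)
      tab <- table(factor(c("ATG", draws), levels = colnames(tallies)))
      tallies[i, ] <- as.integer(tab)
    }
    cds <- Biostrings::DNAStringSet(seqs)
    names(cds) <- rownames(tallies)
    tpm <- matrix(10, n_genes, n_samples,
                  dimnames = list(rownames(tallies),
                                  paste0("S", seq_len(n_samples))))
    meta <- data.frame(sample_id = colnames(tpm), tissue = "pooled",
                       treatment = "all",
                       individual = colnames(tpm),
                       stringsAsFactors = FALSE)
    truth <- list(seed = seed, codon_tallies = tallies, weights = w)
    list(cds = cds, tpm = tpm, meta = meta, truth = truth)
  })
}

#' Simulate DMRs at planted distances from tRNA genes
#'
#' For each requested distance `d`, a DMR of width `width` is placed
#' exactly `d` bp downstream of a randomly chosen gene (`d = 0` places it
#' inside the gene body). Placements are re-drawn (bounded retries) if
#' another gene would be nearer to the DMR than `d`, so the planted
#' distance is also the realised nearest-gene distance.
#'
#' @param genes A [TrnaGeneSet-class].
#' @param planted_distances Non-negative integer distances, one DMR each.
#' @param width DMR width in bp (default 200).
#' @param seed Integer seed.
#' @return List with `dmrs` (`GRanges` with `name`) and `truth`
#'   (`data.frame` of dmr_name, gene_id, distance).
#' @export
simulateDmrs <- function(genes, planted_distances, width = 200L,
                         seed = 1L) {
  stopifnot(all(planted_distances >= 0))
  gr <- granges(genes)
  .withSeed(seed, {
    rows <- list(); ranges <- list()
    for (k in seq_along(planted_distances)) {
      d <- planted_distances[k]
      placed <- FALSE
      for (try in 1:100) {
        i <- sample(length(gr), 1L)
        chrom <- as.character(GenomicRanges::seqnames(gr))[i]
        if (d == 0L) {
          st <- GenomicRanges::start(gr)[i] + 5L
          en <- min(st + width - 1L, GenomicRanges::end(gr)[i])
        } else {
          st <- GenomicRanges::end(gr)[i] + d
          en <- st + width - 1L
        }
        cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en))
        others <- gr[-i]
        same <- others[as.character(
          GenomicRanges::seqnames(others)) == chrom]
        clash <- FALSE
        if (length(same) > 0L) {
          gaps <- pmax(GenomicRanges::start(same) - en,
                       st - GenomicRanges::end(same), 0L)
          clash <- any(gaps < d) ||
            (d == 0L && FALSE)
        }
        if (!clash) {
          ranges[[k]] <- cand
          rows[[k]] <- data.frame(
            dmr_name = paste0("dmr", k),
            gene_id = geneIds(genes)[i],
            distance = d, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place DMR at distance ", d,
                        " after 100 tries")
    }
    dmrs <- GenomicRanges::GRanges(
      unlist(lapply(ranges, function(r)
        as.character(GenomicRanges::seqnames(r)))),
      IRanges::IRanges(
        vapply(ranges, GenomicRanges::start, integer(1)),
        vapply(ranges, GenomicRanges::end, integer(1))))
    mcols(dmrs)$name <- paste0("dmr", seq_along(planted_distances))
    list(dmrs = dmrs, truth = do.call(rbind, rows))
  })
}

#' Simulate reads from sequence groups with known weights
#'
#' Draws reads from group sequences with the given weights, appending the
#' post-transcriptional CCA tail, and records the per-group draw tally so
#' that [assignReads()] can be checked exactly.
#'
#' @param groups A [SequenceGroups-class].
#' @param n_reads Number of reads.
#' @param weights Sampling weights over groups (default uniform).
#' @param seed Integer seed.
#' @return List with `reads` (character) and `truth` (named draw tally).
#' @export
simulateReads <- function(groups, n_reads = 1000L, weights = NULL,
                          seed = 1L) {
  gids <- groupIds(groups)
  if (is.null(weights)) weights <- rep(1, length(gids))
  .withSeed(seed, {
    idx <- sample(seq_along(gids), n_reads, replace = TRUE, prob = weights)
    reads <- paste0(groupSequences(groups)[idx], "CCA")
    tally <- tabulate(idx, nbins = length(gids))
    list(reads = reads,
         truth = stats::setNames(as.integer(tally), gids))
  })
}
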