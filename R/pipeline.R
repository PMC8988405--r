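#' Assemble a pipeline run configuration
#'
#' Bundles input paths, the treatment role mapping and all analysis
#' thresholds with their defaults. Optional inputs (`cds_fasta` /
#' `tpm_tsv`, `dmr_bed`) may be `NULL`; the corresponding stages are then
#' skipped with a notice.
#'
#' @param annotation_gff,genome_fasta tRNA annotation GFF3 and genome (or
#'   per-gene) FASTA.
#' @param counts_tsv,sample_sheet_tsv Raw tRNA count matrix and design
#'   sheet.
#' @param cds_fasta,tpm_tsv,tpm_sample_sheet_tsv CDS set and gene TPM
#'   matrix for codon usage (optional).
#' @param dmr_bed DMR intervals in BED (optional).
#' @param roles Named character: treatment labels for the roles control /
#'   normal / los.
#' @param mito_contig Mitochondrial contig name.
#' @param min_individuals,cpm_threshold,los_min,alpha,min_tpm,min_reps,window
#'   Analysis thresholds (defaults 2, 5, 2, 0.05, 1, 2, 5000).
#' @param seed Integer seed recorded in the manifest.
#' @param outdir Output directory.
#' @return A `list` of class `trna_pipeline_config`.
#' @export
pipelineConfig <- function(annotation_gff, genome_fasta, counts_tsv,
                           sample_sheet_tsv, cds_fasta = NULL,
                           tpm_tsv = NULL, tpm_sample_sheet_tsv = NULL,
                           dmr_bed = NULL,
                           roles = c(control = "Control-AI",
                                     normal = "ART-Normal",
                                     los = "ART-LOS"),
                           mito_contig = "MT", min_individuals = 2L,
                           cpm_threshold = 5, los_min = 2L, alpha = 0.05,
                           min_tpm = 1, min_reps = 2L, window = 5000L,
                           seed = 1L, outdir = "trna_pipeline_out") {
  cfg <- list(annotation_gff = annotation_gff, genome_fasta = genome_fasta,
              counts_tsv = counts_tsv, sample_sheet_tsv = sample_sheet_tsv,
              cds_fasta = cds_fasta, tpm_tsv = tpm_tsv,
              tpm_sample_sheet_tsv = tpm_sample_sheet_tsv,
              dmr_bed = dmr_bed, roles = roles, mito_contig = mito_contig,
              min_individuals = min_individuals,
              cpm_threshold = cpm_threshold, los_min = los_min,
              alpha = alpha, min_tpm = min_tpm, min_reps = min_reps,
              window = window, seed = seed, outdir = outdir)
  class(cfg) <- "trna_pipeline_config"
  cfg
}

.validateConfig <- function(cfg) {
  for (nm in c("annotation_gff", "counts_tsv", "sample_sheet_tsv")) {
    if (is.null(cfg[[nm]]) || !file.exists(cfg[[nm]]))
      stop("required input '", nm, "' missing or not found: ",
           if (is.null(cfg[[nm]])) "(unset)" else cfg[[nm]])
  }
  for (nm in c("genome_fasta", "cds_fasta", "tpm_tsv",
               "tpm_sample_sheet_tsv", "dmr_bed")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("input '", nm, "' not found: ", cfg[[nm]])
  }
  thr <- c("min_individuals", "cpm_threshold", "los_min", "alpha",
           "min_tpm", "min_reps", "window")
  if (any(unlist(cfg[thr]) <= 0)) stop("all thresholds must be positive")
  if (!all(c("control", "normal", "los") %in% names(cfg$roles)))
    stop("roles must name control, normal and los")
  invisible(TRUE)
}

#' Run the full tRNA expression analysis pipeline
#'
#' Executes annotation parsing and sequence collapsing, quantification
#' (CPM, expression flags, isodecoder proportions), differential
#' expression for the three treatment contrasts in each tissue, codon
#' usage with concordance (when CDS/TPM inputs are given), the
#' correlation and set-partition analyses, and DMR proximity (when a BED
#' is given). All outputs are TSVs plus a JSON run manifest recording
#' parameters, input checksums and warnings. Outputs are staged in a
#' temporary directory and only moved to `outdir` on success, so a failed
#' run leaves no partial outputs.
#'
#' @param config A configuration from [pipelineConfig()].
#' @return Invisibly, the manifest list; side effect: files under
#'   `config$outdir`.
#' @export
runPipeline <- function(config) {
  .validateConfig(config)
  warnings_log <- character()
  notices <- character()
  note <- function(msg) {
    notices <<- c(notices, msg)
    message(msg)
  }
  stage_dir <- tempfile("trna_pipeline_stage_")
  dir.create(stage_dir)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  outputs <- character()
  emit <- function(name, writer) {
    path <- file.path(stage_dir, name)
    writer(path)
    outputs <<- c(outputs, name)
  }
  stages <- character()

  withCallingHandlers({
    ## annotation
    genes <- parseTrnaAnnotation(config$annotation_gff,
                                 sequences = config$genome_fasta,
                                 mito_contig = config$mito_contig)
    groups <- collapseIdenticalSequences(genes)
    emit("gene_table.tsv", function(p) writeGeneTable(genes, p))
    emit("groups.tsv", function(p) writeGroupTable(groups, p))
    cn <- copyNumber(genes, "anticodon")
    emit("copy_number.tsv", function(p)
      utils::write.table(data.frame(anticodon = names(cn),
                                    copies = as.integer(cn)),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    stages <- c(stages, "annotation")

    ## quantify
    counts <- readCounts(config$counts_tsv, config$sample_sheet_tsv)
    feats <- rownames(counts)
    if (all(feats %in% geneIds(genes))) {
      g2g <- geneToGroup(groups)
      counts <- aggregateCounts(counts, g2g[feats])
    } else if (!all(feats %in% groupIds(groups))) {
      stop("count features match neither gene ids nor group ids")
    }
    cpm <- cpmNormalize(counts)
    emit("cpm.tsv", function(p) .writeMatrix(assay(cpm), "group_id", p))
    emit("log2cpm.tsv", function(p)
      .writeMatrix(assay(cpmNormalize(counts, log2 = TRUE)),
                   "group_id", p))
    flags <- filterExpressed(counts, config$min_individuals)
    emit("expression_flags.tsv", function(p) .writeFlags(flags, p))
    gene_flags <- geneFlagsFromGroups(flags, groups)
    prop <- isodecoderExpressedProportion(gene_flags, genes)
    emit("isodecoder_proportions.tsv", function(p)
      utils::write.table(prop, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    stages <- c(stages, "quantify")

    ## detest
    tissues <- unique(as.character(colData(counts)$tissue))
    contrasts <- list(c("control", "normal"), c("normal", "los"),
                      c("control", "los"))
    for (tis in tissues) {
      sub <- TrnaCounts(
        assay(counts)[, colData(counts)$tissue == tis, drop = FALSE],
        colData(counts)[colData(counts)$tissue == tis, ], scale = "raw")
      for (ct in contrasts) {
        res <- tryCatch(
          deTest(sub, config$roles, ct, groups = groups,
                 cpm_threshold = config$cpm_threshold,
                 los_min = config$los_min, alpha = config$alpha),
          error = function(e) {
            note(paste0("DE skipped for ", tis, " ", ct[1L], " vs ",
                        ct[2L], ": ", conditionMessage(e)))
            NULL
          })
        if (!is.null(res))
          emit(paste0("de_", tis, "_", ct[1L], "_vs_", ct[2L], ".tsv"),
               function(p) utils::write.table(res, p, sep = "\t",
                                              quote = FALSE,
                                              row.names = FALSE))
      }
    }
    stages <- c(stages, "detest")

    ## codonusage (optional inputs)
    usage_by_group <- NULL
    if (!is.null(config$cds_fasta) && !is.null(config$tpm_tsv)) {
      cds <- Biostrings::readDNAStringSet(config$cds_fasta)
      tpm_df <- utils::read.delim(config$tpm_tsv, check.names = FALSE)
      tpm <- as.matrix(tpm_df[, -1L, drop = FALSE])
      rownames(tpm) <- tpm_df[[1L]]
      tpm_meta <- utils::read.delim(config$tpm_sample_sheet_tsv,
                                    stringsAsFactors = FALSE)
      expr_sets <- expressedGeneSet(tpm, tpm_meta, config$min_tpm,
                                    config$min_reps)
      usage_by_group <- lapply(expr_sets, function(gset) {
        sel <- cds[intersect(names(cds), gset)]
        freq <- codonFrequencies(sel, scope = "per_gene")
        list(pooled = colSums(freq$counts),
             rscu_avg = averagePerGene(rscuValues(freq$counts)),
             rac_avg = averagePerGene(racValues(freq$counts)),
             qc = freq$qc)
      })
      emit("codon_usage.tsv", function(p) {
        rows <- do.call(rbind, lapply(names(usage_by_group), function(g) {
          u <- usage_by_group[[g]]
          sense <- .senseTable()
          data.frame(group = g, codon = sense$codon,
                     amino_acid = sense$amino_acid,
                     count = as.numeric(u$pooled[sense$codon]),
                     rscu_avg = as.numeric(u$rscu_avg[sense$codon]),
                     rac_avg = as.numeric(u$rac_avg[sense$codon]),
                     stringsAsFactors = FALSE)
        }))
        utils::write.table(rows, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      })
      stages <- c(stages, "codonusage")
    } else {
      note("codon usage stage skipped: no CDS/TPM inputs")
    }

    ## correlate
    cor_rows <- list()
    cd <- colData(counts)
    for (tis in tissues) {
      smp <- colnames(counts)[cd$tissue == tis]
      expr <- anticodonMeanCpm(counts, groups, smp)
      cc <- copyNumberExpression(expr, cn)
      cor_rows[[paste0("cn_", tis)]] <- data.frame(
        contrast = paste0("copy_number_vs_expression.", tis),
        n = cc$n, r = cc$r, p = cc$p_value)
      if (!is.null(usage_by_group)) {
        for (trt in unique(as.character(cd$treatment))) {
          key <- paste(tis, trt, sep = ".")
          if (!key %in% names(usage_by_group)) next
          smp2 <- colnames(counts)[cd$tissue == tis & cd$treatment == trt]
          expr2 <- anticodonMeanCpm(counts, groups, smp2)
          upct <- familyPercentages(usage_by_group[[key]]$rscu_avg)
          epct <- familyPercentages(expr2)
          rc <- tryCatch(rscuExpressionCorrelation(upct, epct),
                         error = function(e) NULL)
          if (!is.null(rc))
            cor_rows[[paste0("rscu_", key)]] <- data.frame(
              contrast = paste0("rscu_vs_expression.", key),
              n = rc$n, r = rc$r, p = rc$p_value)
        }
      }
    }
    emit("correlations.tsv", function(p)
      utils::write.table(do.call(rbind, unname(cor_rows)), p, sep = "\t",
                         quote = FALSE, row.names = FALSE))

    part_rows <- list()
    flags_trt <- filterExpressed(counts, config$min_individuals,
                                 within = "treatment")
    for (tis in tissues) {
      cols <- grep(paste0("^", tis, "\\."), colnames(flags_trt),
                   value = TRUE)
      sets <- lapply(cols, function(cl)
        rownames(flags_trt)[flags_trt[, cl]])
      names(sets) <- sub(paste0("^", tis, "\\."), "", cols)
      sp <- sharedUnique(sets)
      sp$scope <- paste0("treatments_within_", tis)
      part_rows[[tis]] <- sp
    }
    if (length(tissues) == 2L) {
      for (trt in unique(as.character(cd$treatment))) {
        sets <- lapply(tissues, function(tis) {
          cl <- paste(tis, trt, sep = ".")
          rownames(flags_trt)[flags_trt[, cl]]
        })
        names(sets) <- tissues
        sp <- sharedUnique(sets)
        sp$scope <- paste0("tissues_within_", trt)
        part_rows[[paste0("t_", trt)]] <- sp
      }
    }
    emit("partitions.tsv", function(p)
      utils::write.table(do.call(rbind, unname(part_rows)), p, sep = "\t",
                         quote = FALSE, row.names = FALSE))
    stages <- c(stages, "correlate")

    ## dmr (optional input)
    if (!is.null(config$dmr_bed)) {
      dmrs <- readBed(config$dmr_bed)
      dmr_report <- genesNearDmrs(genes, dmrs, window = config$window,
                                  groups = groups)
      emit("dmr_report.tsv", function(p)
        utils::write.table(dmr_report, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      stages <- c(stages, "dmr")
    } else {
      note("DMR stage skipped: no BED input")
    }
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  ## manifest + atomic move to outdir
  inputs <- Filter(Negate(is.null),
                   config[c("annotation_gff", "genome_fasta", "counts_tsv",
                            "sample_sheet_tsv", "cds_fasta", "tpm_tsv",
                            "tpm_sample_sheet_tsv", "dmr_bed")])
  manifest <- list(
    package = "isodecodeR",
    version = as.character(utils::packageVersion("isodecodeR")),
    parameters = config[c("roles", "mito_contig", "min_individuals",
                          "cpm_threshold", "los_min", "alpha", "min_tpm",
                          "min_reps", "window", "seed")],
    input_checksums = as.list(tools::md5sum(unlist(inputs))),
    stages = stages,
    outputs = stats::setNames(
      as.list(tools::md5sum(file.path(stage_dir, outputs))), outputs),
    warnings = warnings_log,
    notices = notices)
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs <- c(outputs, "manifest.json")
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  ok <- file.copy(file.path(stage_dir, outputs), config$outdir,
                  overwrite = TRUE)
  if (!all(ok)) stop("failed to move outputs into ", config$outdir)
  invisible(manifest)
}

.writeMatrix <- function(mat, id_col, path) {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.writeFlags <- function(flags, path) {
  df <- data.frame(feature = rep(rownames(flags), ncol(flags)),
                   group = rep(colnames(flags), each = nrow(flags)),
                   expressed = as.vector(flags),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
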