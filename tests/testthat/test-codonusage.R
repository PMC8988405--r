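test_that("the codon table is the standard genetic code", {
  tab <- buildCodonTable()
  expect_identical(nrow(tab), 64L)
  expect_identical(sum(!tab$is_stop), 61L)
  expect_setequal(tab$codon[tab$is_stop], c("TAA", "TAG", "TGA"))
  fam <- table(tab$amino_acid[!tab$is_stop])
  expect_identical(length(fam), 20L)
  expect_identical(as.integer(fam[c("Met", "Trp")]), c(1L, 1L))
  expect_identical(unname(fam[["Leu"]]), 6L)
})

test_that("expressed gene sets follow the inclusive TPM rule", {
  tpm <- matrix(0, 3, 4, dimnames = list(paste0("g", 1:3),
                                         paste0("S", 1:4)))
  tpm["g1", ] <- c(1.0, 1.0, 0, 0)   # exactly at threshold, 2 reps
  tpm["g2", ] <- c(5.0, 0, 0, 0)     # one replicate only
  meta <- data.frame(sample_id = paste0("S", 1:4),
                     tissue = "muscle",
                     treatment = rep(c("Control-AI", "ART-LOS"), each = 2))
  sets <- expressedGeneSet(tpm, meta)
  expect_identical(sets[["muscle.Control-AI"]], "g1")
  expect_identical(sets[["muscle.ART-LOS"]], character(0))
  # brute-force oracle on random patterns
  set.seed(71)
  for (trial in 1:20) {
    tpm <- matrix(rexp(30 * 6, 1 / 2), 30, 6,
                  dimnames = list(paste0("g", 1:30), paste0("S", 1:6)))
    meta <- data.frame(sample_id = paste0("S", 1:6), tissue = "liver",
                       treatment = rep(c("A", "B"), each = 3))
    sets <- expressedGeneSet(tpm, meta, min_tpm = 1, min_reps = 2)
    for (grp in c("A", "B")) {
      cols <- meta$sample_id[meta$treatment == grp]
      manual <- rownames(tpm)[rowSums(tpm[, cols] >= 1) >= 2]
      expect_identical(sets[[paste0("liver.", grp)]], manual)
    }
  }
})

test_that("codon counting drops terminal stops and flags anomalies", {
  cds <- Biostrings::DNAStringSet(c(
    ok = "ATGAAAAAGTAA",            # ATG AAA AAG, stop excluded
    internal = "ATGTAAAAATAA",      # internal TAA counted + flagged
    badlen = "ATGAAAA"))            # length 7, skipped
  expect_warning(res <- codonFrequencies(cds, scope = "per_gene"),
                 "divisible")
  expect_identical(unname(res$counts["ok", c("ATG", "AAA", "AAG", "TAA")]),
                   c(1L, 1L, 1L, 0L))
  expect_identical(unname(res$counts["internal", "TAA"]), 1L)
  expect_setequal(res$qc$issue, c("skipped_length", "internal_stop"))
  expect_identical(res$qc$gene[res$qc$issue == "skipped_length"], "badlen")
  # empty input gives an all-zero pooled profile
  empty <- codonFrequencies(Biostrings::DNAStringSet(), scope = "pooled")
  expect_identical(sum(empty$counts), 0L)
  # ambiguity codes skip the codon, not the gene
  amb <- codonFrequencies(Biostrings::DNAStringSet(c(g = "ATGANNAAA")),
                          scope = "pooled")
  expect_identical(unname(amb$counts["ATG"]), 1L)
  expect_identical(unname(amb$counts["AAA"]), 1L)
  expect_identical(sum(amb$counts), 2L)
})

test_that("codon counts equal generator tallies", {
  sim <- simulateCds(n_genes = 40, seed = 81)
  res <- codonFrequencies(sim$cds, scope = "per_gene")
  expect_identical(res$counts[, colnames(sim$truth$codon_tallies)],
                   sim$truth$codon_tallies)
})

test_that("RSCU and RAC reproduce closed forms", {
  counts <- stats::setNames(rep(0, 61), codons61())
  counts[c("GCT", "GCC", "GCA", "GCG")] <- 25      # uniform Ala family
  counts["AAA"] <- 30; counts["AAG"] <- 10          # biased Lys family
  counts["ATG"] <- 7                                # single-codon family
  rscu <- rscuValues(counts)
  expect_equal(unname(rscu[c("GCT", "GCC", "GCA", "GCG")]), rep(1, 4))
  expect_equal(unname(rscu[c("AAA", "AAG")]), c(1.5, 0.5))
  expect_equal(unname(rscu[["ATG"]]), 1)
  expect_true(is.na(rscu[["TGG"]]))                  # untouched family
  rac <- racValues(counts)
  expect_equal(unname(rac[c("AAA", "AAG")]), c(1, 1 / 3))
  expect_equal(unname(rac[c("GCT", "GCC", "GCA", "GCG")]), rep(1, 4))
})

test_that("RSCU sums to family size and RAC peaks at one", {
  set.seed(83)
  sense <- codons61()
  fam <- buildCodonTable()
  fam <- stats::setNames(fam$amino_acid, fam$codon)[sense]
  for (trial in 1:20) {
    counts <- stats::setNames(rpois(61, 20), sense)
    rscu <- rscuValues(counts)
    rac <- racValues(counts)
    for (f in unique(fam)) {
      idx <- names(fam)[fam == f]
      if (sum(counts[idx]) == 0) next
      expect_equal(sum(rscu[idx]), length(idx), tolerance = 1e-9)
      expect_equal(max(rac[idx]), 1)
      expect_true(all(rac[idx] >= 0 & rac[idx] <= 1))
    }
  }
})

test_that("per-gene averaging is the arithmetic mean over covered genes", {
  m <- rbind(g1 = stats::setNames(rep(2, 61), codons61()),
             g2 = stats::setNames(rep(1, 61), codons61()))
  expect_equal(unname(averagePerGene(m)["AAA"]), 1.5)
  # identical profiles average to themselves
  expect_equal(averagePerGene(m[c(1, 1), ]), m[1, ])
  # NA (family absent in a gene) excluded, not zero-counted
  m2 <- m; m2["g2", "AAA"] <- NA
  expect_equal(unname(averagePerGene(m2)["AAA"]), 2)
  # random profiles match a brute-force mean
  set.seed(85)
  mm <- matrix(runif(50 * 61), 50, 61,
               dimnames = list(paste0("g", 1:50), codons61()))
  expect_equal(averagePerGene(mm), colMeans(mm))
})

test_that("anticodon-codon pairing is an involution on all triplets", {
  expect_identical(unname(anticodonToCodon("GGG")), "CCC")
  expect_identical(unname(anticodonToCodon("GUU")), "AAC")
  all_codons <- buildCodonTable()$codon
  back <- vapply(all_codons, function(cd)
    unname(anticodonToCodon(codonToAnticodon(cd))), character(1))
  expect_identical(unname(back), all_codons)
  expect_identical(anyDuplicated(vapply(all_codons, codonToAnticodon,
                                        character(1))), 0L)
  expect_error(anticodonToCodon("GXT"), "invalid")
})

test_that("wobble decoding follows the position-34 rule table", {
  expect_setequal(wobbleDecodes("UGG"), c("CCA", "CCG"))
  expect_setequal(wobbleDecodes("GCC"), c("GGC", "GGT"))
  expect_setequal(wobbleDecodes("AGG"), c("CCT", "CCC", "CCA"))
  expect_identical(wobbleDecodes("AGG", inosine_at_A34 = FALSE), "CCT")
  # the Watson-Crick codon is always decodable (U stays in under inosine)
  for (ac in vapply(buildCodonTable()$codon, codonToAnticodon,
                    character(1))) {
    expect_true(unname(anticodonToCodon(ac)) %in% wobbleDecodes(ac))
  }
})

test_that("preferred codons take the family argmax with stable ties", {
  counts <- stats::setNames(rep(0, 61), codons61())
  counts["AAA"] <- 30; counts["AAG"] <- 10
  expect_identical(unname(preferredCodons(counts)["Lys"]), "AAA")
  counts["AAG"] <- 30
  expect_identical(unname(preferredCodons(counts)["Lys"]), "AAA")
  expect_true(is.na(preferredCodons(counts)[["Trp"]]))
  # invariant under positive rescaling
  set.seed(87)
  counts2 <- stats::setNames(rpois(61, 50) + 1, codons61())
  expect_identical(preferredCodons(counts2), preferredCodons(counts2 * 7.3))
})

test_that("concordance counts families whose top anticodon matches usage", {
  counts <- stats::setNames(rep(0, 61), codons61())
  counts["CCC"] <- 40; counts["CCA"] <- 10        # Pro prefers CCC
  expr <- c("Pro-GGG" = 100, "Pro-UGG" = 20)
  rep1 <- concordance(expr, counts)
  expect_true(rep1$concordant[rep1$family == "Pro"])
  expr2 <- c("Pro-UGG" = 100, "Pro-GGG" = 20)
  rep2 <- concordance(expr2, counts)
  expect_false(rep2$concordant[rep2$family == "Pro"])
  expect_identical(attr(rep2, "n_families"), 1L)
  expect_true("Lys" %in% attr(rep2, "unexpressed_families"))
})

test_that("a planted 13-of-20 concordant profile is reported as 13", {
  set.seed(89)
  sense <- senseTable61()
  families <- sort(unique(sense$amino_acid))
  concordant_fams <- families[1:13]
  counts <- stats::setNames(rep(1, 61), sense$codon)
  expr <- numeric(0)
  for (f in families) {
    codons <- sort(sense$codon[sense$amino_acid == f])
    top_codon <- codons[1L]
    counts[top_codon] <- 50
    if (f %in% concordant_fams) {
      expr[paste0(f, "-", codonToAnticodon(top_codon))] <- 100
    } else if (length(codons) > 1L) {
      expr[paste0(f, "-", codonToAnticodon(codons[2L]))] <- 100
    } else {
      # single-codon family cannot be made discordant; leave unexpressed
      next
    }
  }
  rep <- concordance(expr, counts)
  expect_identical(attr(rep, "n_concordant"), 13L)
})

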