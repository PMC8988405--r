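test_that("the DE prefilter applies the three-clause rule inclusively", {
  # library size 1e5 so count 1 = 10 CPM; threshold 5 CPM = 0.5 counts
  n_ctrl <- 5; n_norm <- 4; n_los <- 4
  trt <- c(rep("Control-AI", n_ctrl), rep("ART-Normal", n_norm),
           rep("ART-LOS", n_los))
  base <- matrix(100L, 4, 13,
                 dimnames = list(paste0("f", 1:4), paste0("S", 1:13)))
  filler <- matrix(1000000L - colSums(base), 1, 13,
                   dimnames = list("bulk", paste0("S", 1:13)))
  # f1: exactly at threshold in all controls (5 CPM = 5 counts at lib 1e6)
  base["f1", ] <- 0L; base["f1", trt == "Control-AI"] <- 5L
  # f2: above threshold in exactly two LOS samples
  base["f2", ] <- 0L; base["f2", which(trt == "ART-LOS")[1:2]] <- 50L
  # f3: above threshold in one LOS sample only
  base["f3", ] <- 0L; base["f3", which(trt == "ART-LOS")[1]] <- 50L
  # f4: high in all but one control, all but one normal
  base["f4", ] <- 50L
  base["f4", which(trt == "Control-AI")[1]] <- 0L
  base["f4", which(trt == "ART-Normal")[1]] <- 0L
  mat <- rbind(base, filler)
  mat["bulk", ] <- 1000000L - colSums(base)
  x <- toyCounts(mat, tissue = "muscle", treatment = trt,
                 individual = paste0("F", 1:13))
  kept <- dePrefilter(x, rolesDefault, cpm_threshold = 5, los_min = 2)
  expect_true("f1" %in% kept)       # inclusive "at least" in all controls
  expect_true("f2" %in% kept)       # two LOS suffice
  expect_false("f3" %in% kept)
  expect_true("f4" %in% kept)       # >= 2 LOS clause still satisfied
  expect_error(dePrefilter(x, c(control = "Control-AI")), "roles")
})

test_that("the DE prefilter matches brute-force rule evaluation", {
  set.seed(91)
  trt <- rep(c("Control-AI", "ART-Normal", "ART-LOS"), c(5, 4, 4))
  for (trial in 1:20) {
    mat <- matrix(rnbinom(50 * 13, mu = 30, size = 0.5), 50, 13,
                  dimnames = list(paste0("f", 1:50), paste0("S", 1:13)))
    storage.mode(mat) <- "integer"
    x <- toyCounts(mat, tissue = "muscle", treatment = trt,
                   individual = paste0("F", 1:13))
    kept <- dePrefilter(x, rolesDefault)
    cpm <- sweep(mat, 2, colSums(mat), "/") * 1e6
    manual <- apply(cpm, 1, function(v) {
      all(v[trt == "Control-AI"] >= 5) ||
        all(v[trt == "ART-Normal"] >= 5) ||
        sum(v[trt == "ART-LOS"] >= 5) >= 2
    })
    expect_identical(kept, rownames(mat)[manual])
  }
})

test_that("TMM factors are unit for identical and scaled columns", {
  set.seed(11)
  col <- rnbinom(300, mu = 50, size = 2)
  mat <- cbind(S1 = col, S2 = col, S3 = col)
  f <- tmmFactors(mat)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-12)
  # pure depth change, no composition change
  mat2 <- cbind(S1 = col, S2 = 2L * col)
  f2 <- tmmFactors(mat2)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-6)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-12)
})

test_that("TMM factors agree with an independent implementation", {
  skip_if_not_installed("edgeR")
  set.seed(12)
  for (trial in 1:5) {
    mat <- matrix(rnbinom(200 * 6, mu = exp(rnorm(1200, log(80), 1)),
                          size = 5), 200, 6,
                  dimnames = list(paste0("f", 1:200), paste0("s", 1:6)))
    ours <- tmmFactors(mat)
    ref <- edgeR::calcNormFactors(edgeR::DGEList(mat))$samples$norm.factors
    expect_equal(unname(ours), ref, tolerance = 0.05)
  }
})

test_that("moment dispersion recovers simulation truth", {
  set.seed(21)
  n <- 500
  mu <- exp(rnorm(n, log(100), 1))
  pois <- sapply(1:10, function(j) rpois(n, mu))
  dimnames(pois) <- list(paste0("f", 1:n), paste0("s", 1:10))
  expect_lt(commonDispersion(pois, rep(c("a", "b"), each = 5)), 0.05)
  nb <- sapply(1:10, function(j) rnbinom(n, size = 5, mu = mu))
  dimnames(nb) <- dimnames(pois)
  est <- commonDispersion(nb, rep(c("a", "b"), each = 5))
  expect_gt(est, 0.1); expect_lt(est, 0.3)
  # constant matrix has no excess variance
  const <- matrix(7L, 20, 4, dimnames = list(paste0("f", 1:20),
                                             paste0("s", 1:4)))
  expect_identical(commonDispersion(const, rep("a", 4)), 0)
  expect_warning(
    commonDispersion(const, paste0("g", 1:4)), "dispersion")
})

test_that("exact test honours closed-form binomial cases", {
  nf4 <- stats::setNames(rep(1, 4), paste0("s", 1:4))
  m <- matrix(c(5L, 5L, 5L, 5L), 1, 4,
              dimnames = list("f1", paste0("s", 1:4)))
  p <- nbExactTest(m, c("s1", "s2"), c("s3", "s4"), phi = 0,
                   norm_factors = nf4, lib_sizes = rep(100, 4))
  expect_equal(unname(p), 1)
  m2 <- matrix(c(0L, 100L), 1, 2, dimnames = list("f1", c("a", "b")))
  p2 <- nbExactTest(m2, "a", "b", phi = 0, norm_factors = c(a = 1, b = 1),
                    lib_sizes = c(a = 1000, b = 1000))
  expect_lt(unname(p2), 1e-20)
  # all-zero feature
  m3 <- matrix(0L, 1, 2, dimnames = list("f1", c("a", "b")))
  expect_equal(unname(nbExactTest(m3, "a", "b", 0.1,
                                  norm_factors = c(a = 1, b = 1),
                                  lib_sizes = c(a = 10, b = 10))), 1)
  # agreement with exact binomial enumeration on a small case
  m4 <- matrix(c(3L, 9L), 1, 2, dimnames = list("f1", c("a", "b")))
  p4 <- nbExactTest(m4, "a", "b", phi = 0, norm_factors = c(a = 1, b = 1),
                    lib_sizes = c(a = 100, b = 100))
  probs <- dbinom(0:12, 12, 0.5)
  oracle <- sum(probs[probs <= probs[4] * (1 + 1e-10)])
  expect_equal(unname(p4), oracle, tolerance = 1e-12)
})

test_that("exact test is symmetric under group swap", {
  set.seed(33)
  mat <- matrix(rnbinom(50 * 8, mu = 60, size = 8), 50, 8,
                dimnames = list(paste0("f", 1:50), paste0("s", 1:8)))
  a <- paste0("s", 1:4); b <- paste0("s", 5:8)
  nf <- tmmFactors(mat)
  p_ab <- nbExactTest(mat, a, b, 0.15, norm_factors = nf)
  p_ba <- nbExactTest(mat, b, a, 0.15, norm_factors = nf)
  expect_equal(p_ab, p_ba, tolerance = 1e-12)
})

test_that("null type-I error is near nominal across dispersions", {
  for (phi in c(0, 0.1, 0.4)) {
    set.seed(42)
    n <- 1000
    mu <- exp(rnorm(n, log(100), 1))
    lib <- runif(10, 0.7, 1.4)
    mat <- sapply(1:10, function(j) {
      if (phi == 0) rpois(n, mu * lib[j])
      else rnbinom(n, size = 1 / phi, mu = mu * lib[j])
    })
    dimnames(mat) <- list(paste0("f", 1:n), paste0("s", 1:10))
    phihat <- commonDispersion(mat, rep(c("a", "b"), each = 5))
    p <- nbExactTest(mat, paste0("s", 1:5), paste0("s", 6:10), phihat)
    expect_gt(mean(p <= 0.05), 0.03)
    expect_lt(mean(p <= 0.05), 0.07)
  }
})

test_that("BH adjustment matches hand computations and brute force", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(55)
  for (trial in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- bhAdjust(p)
    expect_lt(max(abs(got - bruteBH(p))), 1e-12)
  }
  # independent library cross-check
  p <- runif(200)
  expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("calling requires both p and FDR at alpha, inclusively", {
  res <- data.frame(p_value = c(0.04, 0.05, 0.01),
                    fdr = c(0.06, 0.05, 0.01),
                    log2_fold_change = c(1, -2, 3))
  out <- callDE(res, alpha = 0.05)
  expect_identical(out$called, c(FALSE, TRUE, TRUE))
  expect_identical(out$direction, c("none", "down", "up"))
})

test_that("spiked fold changes are recovered with few false calls", {
  stats <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    mu <- exp(rnorm(n, log(100), 1))
    spiked <- sample(n, 10)
    muB <- mu; muB[spiked] <- muB[spiked] * 4
    lib <- runif(10, 0.7, 1.4)
    mat <- cbind(sapply(1:5, function(j) rnbinom(n, 10, mu = mu * lib[j])),
                 sapply(6:10, function(j) rnbinom(n, 10, mu = muB * lib[j])))
    dimnames(mat) <- list(paste0("f", 1:n), paste0("s", 1:10))
    nf <- tmmFactors(mat)
    phihat <- commonDispersion(mat, rep(c("a", "b"), each = 5), nf)
    p <- nbExactTest(mat, paste0("s", 1:5), paste0("s", 6:10), phihat, nf)
    fdr <- bhAdjust(p)
    called <- which(p <= 0.05 & fdr <= 0.05)
    c(power = sum(called %in% spiked), false = sum(!called %in% spiked))
  })
  expect_gte(median(stats["power", ]), 8)
  expect_lte(median(stats["false", ]), 1)
})

test_that("the full deTest pipeline detects planted group changes", {
  sim <- simulateAnnotation(n_anticodons = 15, dup_fraction = 0.3,
                            seed = 61)
  groups <- collapseIdenticalSequences(sim$genes)
  spike_gid <- groupIds(groups)[5]
  sc <- simulateCounts(groups, phi = 0.05, seed = 62,
                       spike = data.frame(group_id = spike_gid,
                                          tissue = "muscle",
                                          treatment = "ART-LOS", fc = 8))
  cd <- SummarizedExperiment::colData(sc$counts)
  keep <- cd$tissue == "muscle"
  sub <- TrnaCounts(SummarizedExperiment::assay(sc$counts)[, keep],
                    cd[keep, ], scale = "raw")
  res <- deTest(sub, rolesDefault, c("control", "los"), groups = groups)
  expect_true(spike_gid %in% res$group_id[res$called])
  row <- res[res$group_id == spike_gid, ]
  expect_identical(row$direction, "up")
  expect_gt(row$log2_fold_change, 1.5)
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  expect_true(all(c("member_gene_ids", "anticodon") %in% colnames(res)))
})
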