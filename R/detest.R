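#' Expression prefilter for differential testing
#'
#' Keeps a feature iff its CPM reaches `cpm_threshold` in every control
#' sample, or in every normal sample, or in at least `los_min` LOS
#' samples (all thresholds inclusive). The three treatment labels are
#' mapped to the roles control / normal / los via `roles`.
#'
#' @param x A raw [TrnaCounts-class] (typically one tissue).
#' @param roles Named character vector mapping roles to treatment labels,
#'   e.g. `c(control = "Control-AI", normal = "ART-Normal",
#'   los = "ART-LOS")`.
#' @param cpm_threshold CPM cutoff (default 5).
#' @param los_min Minimum qualifying LOS samples (default 2).
#' @return Character vector of kept feature ids.
#' @export
dePrefilter <- function(x, roles, cpm_threshold = 5, los_min = 2L) {
  stopifnot(countScale(x) == "raw")
  if (!all(c("control", "normal", "los") %in% names(roles)))
    stop("roles must map 'control', 'normal' and 'los' to treatment labels")
  trt <- as.character(colData(x)$treatment)
  miss <- setdiff(unname(roles), trt)
  if (length(miss) > 0L)
    stop("treatment label(s) not present in samples: ",
         paste(miss, collapse = ", "))
  cpm <- assay(cpmNormalize(x))
  ctrl <- cpm[, trt == roles[["control"]], drop = FALSE]
  norm <- cpm[, trt == roles[["normal"]], drop = FALSE]
  los <- cpm[, trt == roles[["los"]], drop = FALSE]
  keep <- rowSums(ctrl >= cpm_threshold) == ncol(ctrl) |
    rowSums(norm >= cpm_threshold) == ncol(norm) |
    rowSums(los >= cpm_threshold) >= los_min
  rownames(cpm)[keep]
}

#' Trimmed mean of M-values normalisation factors
#'
#' Re-implementation of TMM scaling: the reference sample is the column
#' whose upper-quartile count fraction is closest to the mean upper
#' quartile (lowest index on ties); per-sample log2 count-fraction ratios
#' (M) are trimmed by `logratio_trim` on each side and by `abs_trim` on
#' mean abundance (A), then combined by a precision-weighted mean.
#' Factors are rescaled so their geometric mean is one.
#'
#' @param x A raw [TrnaCounts-class] or a count matrix.
#' @param logratio_trim Two-sided trim fraction on M (default 0.3).
#' @param abs_trim Two-sided trim fraction on A (default 0.05).
#' @return Named numeric vector of per-sample factors.
#' @export
tmmFactors <- function(x, logratio_trim = 0.3, abs_trim = 0.05) {
  mat <- if (is(x, "TrnaCounts")) assay(x) else as.matrix(x)
  stopifnot(ncol(mat) >= 2L)
  lib <- colSums(mat)
  zero_col <- lib == 0
  if (any(zero_col))
    warning("all-zero column(s): ",
            paste(colnames(mat)[zero_col], collapse = ", "))
  uq <- vapply(seq_len(ncol(mat)), function(j) {
    if (zero_col[j]) return(NA_real_)
    stats::quantile(mat[, j], 0.75, names = FALSE) / lib[j]
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq, na.rm = TRUE)))
  f <- vapply(seq_len(ncol(mat)), function(j) {
    if (zero_col[j] || j == ref) return(1)
    .tmmPair(mat[, j], mat[, ref], lib[j], lib[ref],
             logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(mat))
}

.tmmPair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  # asymptotic variance of M (delta method), used as precision weight
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2) || sum(1 / v[keep2]) == 0) return(1)
  2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' Moment estimate of the common negative-binomial dispersion
#'
#' Pools a method-of-moments estimate of the dispersion phi (variance =
#' mu + phi * mu^2) across all features, computed on counts rescaled to a
#' common effective library size, and floored at zero.
#'
#' @param x A raw [TrnaCounts-class] or count matrix.
#' @param groups Sample group labels (one per column); defaults to the
#'   `treatment` design column.
#' @param norm_factors Optional per-sample normalisation factors
#'   (defaults to [tmmFactors()]).
#' @return Non-negative scalar phi.
#' @export
commonDispersion <- function(x, groups = NULL, norm_factors = NULL) {
  mat <- if (is(x, "TrnaCounts")) assay(x) else as.matrix(x)
  if (is.null(groups)) {
    stopifnot(is(x, "TrnaCounts"))
    groups <- as.character(colData(x)$treatment)
  }
  if (is.null(norm_factors)) norm_factors <- tmmFactors(mat)
  eff <- colSums(mat) * norm_factors
  common <- exp(mean(log(eff[eff > 0])))
  z <- sweep(mat, 2L, common / eff, "*")
  num <- 0; den <- 0; any_group <- FALSE
  for (g in unique(groups)) {
    cols <- which(groups == g)
    n <- length(cols)
    if (n < 2L) next
    any_group <- TRUE
    m <- rowMeans(z[, cols, drop = FALSE])
    v <- apply(z[, cols, drop = FALSE], 1L, stats::var)
    w <- n - 1L
    num <- num + w * sum(v - m)
    den <- den + w * sum(m^2)
  }
  if (!any_group) {
    warning("no group with >= 2 samples; dispersion set to 0")
    return(0)
  }
  max(0, num / den)
}

#' Negative-binomial conditional exact test
#'
#' Two-sided exact test per feature between two sample groups. Counts are
#' rescaled to a common effective library size (deterministic half-up
#' rounding); under the null, the group-A sum conditioned on the total
#' follows the convolution ratio of two negative binomials with common
#' dispersion `phi` (a binomial split when `phi = 0`). The p-value is the
#' summed probability of all outcomes at most as likely as the observed
#' one.
#'
#' @param x A raw [TrnaCounts-class] or count matrix.
#' @param samples_a,samples_b Sample ids (column names) of the two groups.
#' @param phi Common dispersion.
#' @param norm_factors Optional per-sample factors over all columns of
#'   `x`; defaults to [tmmFactors()] on the two groups.
#' @param lib_sizes Optional per-sample library sizes (defaults to
#'   column sums).
#' @return Numeric vector of p-values in (0, 1], named by feature.
#' @export
nbExactTest <- function(x, samples_a, samples_b, phi, norm_factors = NULL,
                        lib_sizes = NULL) {
  mat <- if (is(x, "TrnaCounts")) assay(x) else as.matrix(x)
  stopifnot(all(c(samples_a, samples_b) %in% colnames(mat)))
  mat <- mat[, c(samples_a, samples_b), drop = FALSE]
  if (is.null(norm_factors)) norm_factors <- tmmFactors(mat)
  else {
    if (is.null(names(norm_factors)))
      names(norm_factors) <- colnames(mat)
    norm_factors <- norm_factors[colnames(mat)]
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(mat)
  else {
    if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(mat)
    lib_sizes <- lib_sizes[colnames(mat)]
  }
  eff <- lib_sizes * norm_factors
  eff[eff == 0] <- 1
  common <- exp(mean(log(eff)))
  z <- floor(sweep(mat, 2L, common / eff, "*") + 0.5)
  n_a <- length(samples_a); n_b <- length(samples_b)
  a_sum <- rowSums(z[, samples_a, drop = FALSE])
  t_sum <- a_sum + rowSums(z[, samples_b, drop = FALSE])
  p <- vapply(seq_along(t_sum), function(i) {
    .exactCondP(a_sum[i], t_sum[i], n_a, n_b, phi)
  }, numeric(1))
  stats::setNames(pmin(pmax(p, .Machine$double.xmin), 1), rownames(mat))
}

.exactCondP <- function(a, t, n_a, n_b, phi) {
  if (t == 0) return(1)
  xs <- .supportWindow(a, t, n_a, n_b, phi)
  if (phi == 0) {
    lp <- stats::dbinom(xs, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    mu <- t / (n_a + n_b)
    lp <- stats::dnbinom(xs, size = n_a / phi, mu = mu * n_a, log = TRUE) +
      stats::dnbinom(t - xs, size = n_b / phi, mu = mu * n_b, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(a, xs)]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

.supportWindow <- function(a, t, n_a, n_b, phi) {
  if (t <= 1e5L) return(0:t)
  pa <- n_a / (n_a + n_b)
  mu <- t / (n_a + n_b)
  s <- sqrt(t * pa * (1 - pa) * (1 + phi * mu))
  lo <- max(0, floor(t * pa - 60 * s))
  hi <- min(t, ceiling(t * pa + 60 * s))
  lo <- min(lo, a); hi <- max(hi, a)
  lo:hi
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return FDR-adjusted values in the input order.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Call differential expression
#'
#' A feature is called iff both its p-value and its FDR are at or below
#' `alpha`; direction is the sign of the log2 fold change of called
#' features, `"none"` otherwise.
#'
#' @param results `data.frame` with columns `p_value`, `fdr`,
#'   `log2_fold_change`.
#' @param alpha Significance level (default 0.05, inclusive).
#' @return `results` with columns `called` and `direction` added.
#' @export
callDE <- function(results, alpha = 0.05) {
  called <- results$p_value <= alpha & results$fdr <= alpha
  direction <- ifelse(!called, "none",
                      ifelse(results$log2_fold_change >= 0, "up", "down"))
  results$called <- called
  results$direction <- direction
  results
}

#' Differential expression between two treatment roles
#'
#' Full testing pipeline at sequence-group level: expression prefilter,
#' TMM factors, pooled moment dispersion, conditional exact test,
#' Benjamini-Hochberg adjustment and calling. Fold changes are computed on
#' mean CPM with a 0.5 pseudocount (`b` over `a`).
#'
#' @param x A raw [TrnaCounts-class], typically one tissue.
#' @param roles Role mapping as in [dePrefilter()].
#' @param contrast Length-2 character: role names `(a, b)` to compare.
#' @param groups Optional [SequenceGroups-class] to annotate results with
#'   member loci and anticodons.
#' @param cpm_threshold,los_min Prefilter parameters.
#' @param alpha Calling threshold.
#' @param phi Common dispersion; estimated from the contrast samples when
#'   `NULL`.
#' @param offsets Optional per-sample multiplicative normalisation
#'   offsets (e.g. externally computed unwanted-variation factors),
#'   replacing the TMM factors.
#' @return `data.frame` with one row per tested sequence group.
#' @export
deTest <- function(x, roles, contrast = c("control", "los"), groups = NULL,
                   cpm_threshold = 5, los_min = 2L, alpha = 0.05,
                   phi = NULL, offsets = NULL) {
  stopifnot(length(contrast) == 2L, all(contrast %in% names(roles)))
  kept <- dePrefilter(x, roles, cpm_threshold, los_min)
  if (length(kept) == 0L) stop("no feature passes the expression prefilter")
  trt <- as.character(colData(x)$treatment)
  samples_a <- colnames(x)[trt == roles[[contrast[1L]]]]
  samples_b <- colnames(x)[trt == roles[[contrast[2L]]]]
  sub <- TrnaCounts(assay(x)[kept, c(samples_a, samples_b), drop = FALSE],
                    colData(x)[c(samples_a, samples_b), ], scale = "raw")
  nf <- if (is.null(offsets)) tmmFactors(sub)
        else offsets[colnames(sub)]
  lab <- c(rep("a", length(samples_a)), rep("b", length(samples_b)))
  if (is.null(phi)) phi <- commonDispersion(assay(sub), lab, nf)
  pv <- nbExactTest(sub, samples_a, samples_b, phi, norm_factors = nf)
  cpm <- assay(cpmNormalize(sub))
  mean_a <- rowMeans(cpm[, samples_a, drop = FALSE])
  mean_b <- rowMeans(cpm[, samples_b, drop = FALSE])
  res <- data.frame(
    group_id = kept,
    mean_cpm_a = mean_a, mean_cpm_b = mean_b,
    log2_fold_change = log2((mean_b + 0.5) / (mean_a + 0.5)),
    p_value = unname(pv), fdr = bhAdjust(unname(pv)),
    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    info <- groupInfo(groups)
    idx <- match(res$group_id, info$group_id)
    res$anticodon <- info$anticodon[idx]
    res$amino_acid <- info$amino_acid[idx]
    res$member_gene_ids <- vapply(info$members[idx], paste, character(1),
                                  collapse = ",")
  }
  res <- callDE(res, alpha)
  attr(res, "phi") <- phi
  rownames(res) <- NULL
  res
}
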