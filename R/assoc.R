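# Statistical primitives shared by all pipeline stages: the GLM score test
# for eQTL mapping, the allelic case-control chi-squared test, genomic
# control (lambda and its rescaling to a 1000/1000 cohort), empirical
# permutation p values, permutation-based FDR, BH adjustment, Spearman rank
# correlation and Fisher's exact test.

# Median of the chi-squared distribution with 1 df; denominator of the
# genomic-control inflation estimator.
.chi2_1df_median <- 0.4549364231

#' Rao score test for adding genotype to a Gaussian GLM
#'
#' Fits the covariate-only null model of expression by least squares and
#' tests the addition of the genotype dosage with Rao's score statistic
#' (1 df), using the null-model (maximum-likelihood) variance estimate. The
#' statistic equals `n` times the squared partial correlation between
#' expression and genotype given the covariates. The p value is the upper
#' tail of the 1-df chi-squared distribution (one-tailed in the chi-squared
#' score, as is conventional for this test).
#'
#' Samples with missing genotype, expression or covariate values are removed
#' pairwise before testing.
#'
#' @param expression numeric vector of normalized expression values.
#' @param genotype numeric dosage vector (0/1/2, `NA` allowed).
#' @param covariates optional numeric matrix/data.frame of covariates (an
#'   intercept is always added); must be full rank.
#' @return list with elements `chi2`, `p` and `n` (samples analysed).
#' @export
score_test_glm <- function(expression, genotype, covariates = NULL) {
  y <- as.numeric(expression)
  g <- as.numeric(genotype)
  if (length(y) != length(g)) stop("expression and genotype lengths differ")
  if (is.null(covariates)) {
    X <- matrix(1, length(y), 1)
  } else {
    X <- cbind(1, as.matrix(covariates))
    storage.mode(X) <- "double"
  }
  keep <- !is.na(y) & !is.na(g) & complete.cases(X)
  y <- y[keep]; g <- g[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n < ncol(X) + 1) stop("too few complete samples for the score test")
  if (length(unique(g)) < 2) stop("degenerate genotype: monomorphic dosage")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate matrix")
  e <- qr.resid(qx, y)
  gt <- qr.resid(qx, g)
  ss_g <- sum(gt^2)
  ss_e <- sum(e^2)
  if (ss_g <= 1e-12 * sum(g^2) || ss_e <= 0) {
    chi2 <- 0
  } else {
    chi2 <- n * (sum(gt * e)^2) / (ss_g * ss_e)
  }
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), n = n)
}

#' Allelic case-control chi-squared association test
#'
#' Forms the 2x2 allele-count table (REF vs ALT alleles in cases vs controls)
#' from dosages and returns the Pearson chi-squared statistic with 1 df,
#' without continuity correction by default. The statistic is invariant to
#' swapping which allele is counted.
#'
#' @param case_dosages,control_dosages dosage vectors in \{0, 1, 2\};
#'   missing values are excluded.
#' @param yates apply Yates' continuity correction (off by default; exposed
#'   for sensitivity analysis only).
#' @return list with elements `chi2` and `p` (upper tail, 1 df).
#' @export
allelic_chi2 <- function(case_dosages, control_dosages, yates = FALSE) {
  ca <- case_dosages[!is.na(case_dosages)]
  co <- control_dosages[!is.na(control_dosages)]
  if (length(ca) == 0 || length(co) == 0) {
    stop("both case and control groups must be non-empty")
  }
  if (!all(c(ca, co) %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
  a <- sum(ca); b <- 2 * length(ca) - a      # ALT, REF alleles in cases
  c_ <- sum(co); d <- 2 * length(co) - c_    # ALT, REF alleles in controls
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) stop("undefined statistic: zero margin")
  dev <- abs(a * d - b * c_)
  if (yates) dev <- max(0, dev - n / 2)
  chi2 <- n * dev^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / 0.4549364231`, the median-based genomic-control
#' estimator for 1-df statistics.
#'
#' @param chi2_values non-empty numeric vector of 1-df chi-squared values.
#' @return lambda (positive scalar).
#' @export
genomic_inflation <- function(chi2_values) {
  chi2_values <- chi2_values[!is.na(chi2_values)]
  if (length(chi2_values) == 0) stop("empty chi-squared vector")
  median(chi2_values) / .chi2_1df_median
}

#' Rescale an inflation factor to a 1000-case / 1000-control cohort
#'
#' `lambda_1000 = 1 + (lambda - 1) * ((1/n_cases + 1/n_controls) /
#' (1/1000 + 1/1000))`.
#'
#' @param lam inflation factor (> 0).
#' @param n_cases,n_controls cohort sizes (>= 1).
#' @return rescaled inflation factor.
#' @export
lambda_1000 <- function(lam, n_cases, n_controls) {
  if (!is.numeric(lam) || lam <= 0) stop("lambda must be positive")
  if (n_cases < 1 || n_controls < 1) stop("case/control counts must be >= 1")
  1 + (lam - 1) * ((1 / n_cases + 1 / n_controls) / (1 / 1000 + 1 / 1000))
}

#' Empirical permutation p value
#'
#' The fraction of permuted statistics strictly greater than the observed
#' one; ties count as not greater, so the value can be exactly zero. The
#' conservative `(b + 1) / (B + 1)` variant (with `b` the number of permuted
#' values greater than or equal to the observed) is attached as attribute
#' `conservative`.
#'
#' @param observed observed statistic.
#' @param permuted non-empty vector of statistics from permuted data.
#' @return fraction in \[0, 1\] with attribute `conservative`.
#' @export
empirical_p <- function(observed, permuted) {
  if (length(permuted) == 0) stop("permuted vector is empty")
  p <- sum(permuted > observed) / length(permuted)
  attr(p, "conservative") <-
    (sum(permuted >= observed) + 1) / (length(permuted) + 1)
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p values (capped at 1), returned in the input
#' order.
#'
#' @param pvals numeric vector of p values in \[0, 1\].
#' @return adjusted p values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Permutation-based FDR for a family of tests
#'
#' Plug-in estimator from a pooled permutation null: for an observed p value
#' `t`, `FDR(t) = min(1, (count(permuted <= t) / n_perms) /
#' max(count(observed <= t), 1))`, then monotonized so the estimate is
#' non-decreasing in `t` (q-value style: each value is the minimum plug-in
#' estimate at or above its threshold).
#'
#' @param observed_p observed p values (one per test).
#' @param permuted_p_pool pooled p values from `n_perms` label permutations
#'   of the whole test family.
#' @param n_perms number of permutations that produced the pool.
#' @param threshold significance threshold on the FDR (default 0.10).
#' @return data.frame with columns `p`, `fdr`, `significant`, rows in input
#'   order.
#' @export
permutation_fdr <- function(observed_p, permuted_p_pool, n_perms,
                            threshold = 0.10) {
  if (n_perms < 1) stop("n_perms must be >= 1")
  m <- length(observed_p)
  if (m == 0) {
    return(data.frame(p = numeric(), fdr = numeric(),
                      significant = logical()))
  }
  sp <- sort(permuted_p_pool)
  so <- sort(observed_p)
  v <- findInterval(observed_p, sp) / n_perms   # E[# false at threshold p_i]
  r <- pmax(findInterval(observed_p, so), 1L)   # # observed at threshold
  fdr <- pmin(1, v / r)
  ord <- order(observed_p)
  fdr_sorted <- fdr[ord]
  fdr_sorted <- rev(cummin(rev(fdr_sorted)))
  fdr[ord] <- fdr_sorted
  data.frame(p = observed_p, fdr = fdr, significant = fdr < threshold)
}

#' Spearman rank correlation with a large-sample p value
#'
#' Average ranks are used for ties; the p value comes from the standard
#' large-sample t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with elements `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities less than or equal to that of the
#' observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided exact p value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  fisher.test(table)$p.value
}
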