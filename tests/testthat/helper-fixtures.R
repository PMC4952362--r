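# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A genotype matrix directly from a dosage matrix (ids and positions
# synthesised; one chromosome, evenly spaced).
make_geno <- function(dosage, chrom = "chr1", spacing = 1000L,
                      ids = NULL) {
  m <- ncol(dosage)
  if (is.null(ids)) ids <- sprintf("snp%03d", seq_len(m))
  colnames(dosage) <- ids
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  geno_matrix(dosage,
              data.frame(snp_id = ids, chrom = chrom,
                         pos = seq_len(m) * spacing, ref = "A", alt = "G",
                         stringsAsFactors = FALSE))
}

# Random dosage matrix with independent SNPs at given MAF.
random_dosage <- function(n, m, maf = 0.3, seed = 1) {
  withr::with_seed(seed, {
    matrix(rbinom(n * m, 2, maf), nrow = n)
  })
}

# Covariate table matching a genotype matrix's samples.
make_covars <- function(geno, seed = 1) {
  n <- nrow(geno$dosage)
  withr::with_seed(seed, {
    data.frame(sample = geno_samples(geno), status = rbinom(n, 1, 0.5),
               sex = rbinom(n, 1, 0.5), age = round(runif(n, 20, 70)),
               stringsAsFactors = FALSE)
  })
}

# A small config with reduced permutation counts for fast unit tests.
small_config <- function(...) {
  run_config(seed = 1, n_perms_eqtl = 60, n_perms_set = 200,
             n_iter_null = 200, ...)
}

# A null case-control cohort: independent genotypes, random labels.
null_cohort <- function(n_cases, n_controls, m, maf = 0.3, seed = 1) {
  n <- n_cases + n_controls
  geno <- make_geno(random_dosage(n, m, maf, seed))
  phen <- data.frame(sample = geno_samples(geno),
                     case = rep(c(1L, 0L), c(n_cases, n_controls)),
                     stringsAsFactors = FALSE)
  case_control_cohort(geno, phen)
}

# Independent multiple-correlation oracle via lm().
oracle_multiple_R <- function(target, basis) {
  if (NCOL(basis) == 0) return(0)
  fit <- stats::lm(target ~ as.matrix(basis))
  sqrt(max(0, suppressWarnings(summary(fit))$r.squared))
}

# Independent score-test oracle: n times the squared partial correlation,
# from two explicit lm() residualisations.
oracle_score_chi2 <- function(y, g, X = NULL) {
  if (is.null(X)) {
    ry <- y - mean(y)
    rg <- g - mean(g)
  } else {
    ry <- stats::resid(stats::lm(y ~ as.matrix(X)))
    rg <- stats::resid(stats::lm(g ~ as.matrix(X)))
  }
  length(y) * stats::cor(ry, rg)^2
}
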