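# cis window arithmetic, the eQTL mapper and its permutation FDR, best-SNP
# extraction, subgroup slopes and exhaustive variable selection.

test_that("cis windows follow the radius rule and clamp at 1", {
  g <- list(chrom = "chr1", start_bp = 1000000L, end_bp = 1010000L)
  w <- define_cis_window(g, 100000L)
  expect_equal(w$lo_bp, 900000L)
  expect_equal(w$hi_bp, 1110000L)
  w0 <- define_cis_window(g, 0L)
  expect_equal(c(w0$lo_bp, w0$hi_bp), c(1000000L, 1010000L))
  g2 <- list(chrom = "chr1", start_bp = 50000L, end_bp = 60000L)
  expect_equal(define_cis_window(g2, 100000L)$lo_bp, 1L)
  expect_error(define_cis_window(g, -5), ">= 0")
})

# A compact mapping fixture: 6 genes x 3 independent SNPs, one planted eQTL.
eqtl_fixture <- function(seed = 1, beta = 1, noise = 1, n = 200) {
  emap <- data.frame(gene = "G002", snp = "G002_S02", cell_type = "CD4",
                     beta = beta, stringsAsFactors = FALSE)
  sc <- sim_scenario(n_samples = n, n_genes = 6, snps_per_gene_region = 3,
                     ld_rho = 0, maf_range = c(0.15, 0.4),
                     eqtl_map = emap, noise_sd = noise)
  geno <- simulate_genotypes(sc, seed)
  cv <- simulate_covariates(sc, seed + 1)
  expr <- simulate_expression(geno, cv, sc, "CD4", seed + 2)
  list(sc = sc, geno = geno, cv = cv, expr = expr,
       genes = scenario_gene_annotations(sc))
}

test_that("mapper tests only cis SNPs above the MAF floor", {
  fx <- eqtl_fixture(seed = 10)
  # force one SNP below the 5 % floor: MAF 0.04 must be excluded
  d <- fx$geno$dosage
  d[, "G001_S01"] <- 0
  d[seq_len(round(0.08 * nrow(d))), "G001_S01"] <- 1
  geno <- geno_matrix(d, fx$geno$snps)
  cfg <- small_config()
  tab <- map_cis_eqtls(fx$expr, geno, fx$cv, fx$genes, cfg, 5)
  expect_false("G001_S01" %in% tab$snp_id)
  expect_true("G001_S02" %in% tab$snp_id)
  # every tested SNP lies in its gene's cis window
  for (r in seq_len(nrow(tab))) {
    g <- fx$genes[fx$genes$gene_id == tab$gene_id[r], ]
    w <- define_cis_window(g, cfg$cis_radius_bp)
    pos <- geno$snps$pos[geno$snps$snp_id == tab$snp_id[r]]
    expect_true(pos >= w$lo_bp && pos <= w$hi_bp)
  }
})

test_that("a strongly planted eQTL is recovered as significant", {
  for (s in c(20, 40, 60)) {
    fx <- eqtl_fixture(seed = s, beta = 1)
    tab <- map_cis_eqtls(fx$expr, fx$geno, fx$cv, fx$genes, small_config(),
                         s)
    hit <- tab[tab$gene_id == "G002" & tab$snp_id == "G002_S02", ]
    expect_true(hit$significant)
    expect_gt(hit$beta_all, 0.6)
  }
})

test_that("the vectorised mapper equals the scalar score test", {
  fx <- eqtl_fixture(seed = 30)
  tab <- map_cis_eqtls(fx$expr, fx$geno, fx$cv, fx$genes, small_config(), 5)
  Xc <- as.matrix(fx$cv[match(rownames(fx$expr), fx$cv$sample),
                        c("status", "sex", "age", "batch")])
  for (r in sample(seq_len(nrow(tab)), 6)) {
    st <- score_test_glm(fx$expr[, tab$gene_id[r]],
                         fx$geno$dosage[, tab$snp_id[r]], Xc)
    expect_equal(tab$chi2[r], st$chi2, tolerance = 1e-10)
    expect_equal(tab$p[r], st$p, tolerance = 1e-10)
  }
})

test_that("mapper chi2 is invariant to affine rescaling of expression", {
  fx <- eqtl_fixture(seed = 35)
  cfg <- small_config()
  t1 <- map_cis_eqtls(fx$expr, fx$geno, fx$cv, fx$genes, cfg, 5)
  expr2 <- expr_matrix(3 * unclass(fx$expr) - 10, "CD4")
  t2 <- map_cis_eqtls(expr2, fx$geno, fx$cv, fx$genes, cfg, 5)
  expect_equal(t1$chi2, t2$chi2, tolerance = 1e-9)
})

test_that("discoveries shrink as maf_min rises and threshold falls", {
  fx <- eqtl_fixture(seed = 45, beta = 0.8)
  n_disc <- function(maf_min, thr) {
    cfg <- run_config(seed = 1, n_perms_eqtl = 60, maf_min = maf_min,
                      eqtl_fdr_threshold = thr)
    tab <- map_cis_eqtls(fx$expr, fx$geno, fx$cv, fx$genes, cfg, 5)
    sum(tab$significant)
  }
  expect_gte(n_disc(0.05, 0.10), n_disc(0.25, 0.10))
  expect_gte(n_disc(0.05, 0.10), n_disc(0.05, 0.02))
})

test_that("mapper requires shared samples and enough of them", {
  fx <- eqtl_fixture(seed = 50, n = 30)
  cv_bad <- fx$cv
  cv_bad$sample <- paste0("X", cv_bad$sample)
  expect_error(map_cis_eqtls(fx$expr, fx$geno, cv_bad, fx$genes,
                             small_config(), 5), "no shared samples")
  fx2 <- eqtl_fixture(seed = 51, n = 25)
  expr_few <- expr_matrix(unclass(fx2$expr)[1:12, ], "CD4")
  expect_error(map_cis_eqtls(expr_few, fx2$geno, fx2$cv, fx2$genes,
                             small_config(), 5), "at least 20")
})

test_that("best SNP extraction honours p, chi2 and id tie-breaks", {
  tab <- data.frame(
    gene_id = c("GA", "GA", "GA", "GB"),
    snp_id = c("s2", "s1", "s3", "s9"),
    cell_type = "CD4",
    chi2 = c(9, 9, 4, 2), p = c(0.002, 0.002, 0.04, 0.2),
    fdr = c(0.01, 0.01, 0.1, 0.5),
    significant = c(TRUE, TRUE, FALSE, FALSE),
    beta_all = 1, stringsAsFactors = FALSE)
  best <- best_snp_per_gene(tab)
  expect_equal(nrow(best), 2)
  # equal p and chi2: lexicographically smaller id wins
  expect_equal(best$snp_id[best$gene_id == "GA"], "s1")
  # single tested SNP: that SNP
  expect_equal(best$snp_id[best$gene_id == "GB"], "s9")
  fm <- attr(best, "fdr_matrix")
  expect_equal(dim(fm), c(2, 1))
  expect_equal(fm["GA", "CD4"], -log10(0.01))
})

test_that("best SNP extraction picks the planted strongest SNP", {
  hits <- vapply(1:5, function(s) {
    emap <- data.frame(gene = c("G001", "G001"),
                       snp = c("G001_S01", "G001_S03"),
                       cell_type = "CD4", beta = c(1.2, 0.3),
                       stringsAsFactors = FALSE)
    sc <- sim_scenario(n_samples = 500, n_genes = 2,
                       snps_per_gene_region = 3, ld_rho = 0,
                       maf_range = c(0.2, 0.4), eqtl_map = emap)
    geno <- simulate_genotypes(sc, 100 + s)
    cv <- simulate_covariates(sc, 200 + s)
    expr <- simulate_expression(geno, cv, sc, "CD4", 300 + s)
    tab <- map_cis_eqtls(expr, geno, cv, scenario_gene_annotations(sc),
                         small_config(), s)
    best <- best_snp_per_gene(tab)
    best$snp_id[best$gene_id == "G001"] == "G001_S01"
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("subgroup slopes agree when the effect is shared, NA when absent", {
  emap <- data.frame(gene = "G001", snp = "G001_S01", cell_type = "CD4",
                     beta = 1, stringsAsFactors = FALSE)
  sc <- sim_scenario(n_samples = 400, n_genes = 2, snps_per_gene_region = 2,
                     maf_range = c(0.2, 0.4), eqtl_map = emap)
  geno <- simulate_genotypes(sc, 111)
  cv <- simulate_covariates(sc, 112)
  expr <- simulate_expression(geno, cv, sc, "CD4", 113)
  tab <- data.frame(gene_id = "G001", snp_id = "G001_S01",
                    cell_type = "CD4", chi2 = 50, p = 1e-10, fdr = 0.001,
                    significant = TRUE, beta_all = 1,
                    stringsAsFactors = FALSE)
  conc <- subgroup_concordance(tab, expr, geno, cv, "status")
  expect_equal(nrow(conc), 1)
  # equal planted beta: both group slopes near 1
  expect_lt(abs(conc$beta1 - 1), 3 * conc$se1)
  expect_lt(abs(conc$beta2 - 1), 3 * conc$se2)
  # monomorphic genotype within one group -> missing slope with reason
  d <- geno$dosage
  d[cv$status == 1, "G001_S01"] <- 1
  conc2 <- subgroup_concordance(tab, expr, geno_matrix(d, geno$snps), cv,
                                "status")
  expect_true(is.na(conc2$beta2))
  expect_match(conc2$note, "monomorphic")
})

test_that("null subgroup has slope consistent with zero", {
  sc <- sim_scenario(n_samples = 400, n_genes = 2, snps_per_gene_region = 2,
                     maf_range = c(0.2, 0.4))
  geno <- simulate_genotypes(sc, 121)
  cv <- simulate_covariates(sc, 122)
  expr <- simulate_expression(geno, cv, sc, "CD4", 123)
  tab <- data.frame(gene_id = "G001", snp_id = "G001_S01",
                    cell_type = "CD4", chi2 = 1, p = 0.3, fdr = 0.05,
                    significant = TRUE, beta_all = 0,
                    stringsAsFactors = FALSE)
  conc <- subgroup_concordance(tab, expr, geno, cv, "status")
  expect_lt(abs(conc$beta1), 3 * conc$se1)
  expect_lt(abs(conc$beta2), 3 * conc$se2)
})

test_that("exhaustive selection recovers the causal SNP and prunes nulls", {
  withr::with_seed(131, {
    recovered <- vapply(1:10, function(s) {
      n <- 300
      G <- matrix(rbinom(n * 4, 2, 0.3), n,
                  dimnames = list(NULL, paste0("s", 1:4)))
      y <- 8 + 1 * G[, "s2"] + rnorm(n)
      sel <- exhaustive_selection(y, G)
      identical(sel$selected, "s2")
    }, logical(1))
    expect_gte(sum(recovered), 9)
    # all-null candidates: covariate-only model usually wins
    empty <- vapply(1:10, function(s) {
      n <- 300
      G <- matrix(rbinom(n * 4, 2, 0.3), n,
                  dimnames = list(NULL, paste0("s", 1:4)))
      length(exhaustive_selection(rnorm(n), G)$selected) == 0
    }, logical(1))
    expect_gte(sum(empty), 8)
  })
})

test_that("exhaustive selection agrees with an independent BIC oracle", {
  withr::with_seed(132, {
    n <- 150
    G <- matrix(rbinom(n * 4, 2, 0.3), n,
                dimnames = list(NULL, paste0("s", 1:4)))
    X <- cbind(cov1 = rnorm(n))
    y <- 8 + 0.8 * G[, "s1"] - 0.6 * G[, "s3"] + 0.5 * X[, 1] + rnorm(n)
    sel <- exhaustive_selection(y, G, X)
    # oracle: stats::BIC over lm() fits of every subset
    best_bic <- Inf; best_set <- NULL
    for (mask in 0:15) {
      ss <- which(bitwAnd(mask, 2^(0:3)) > 0)
      dat <- data.frame(y = y, X, G[, ss, drop = FALSE])
      b <- BIC(lm(y ~ ., data = dat))
      if (b < best_bic - 1e-9) {
        best_bic <- b; best_set <- sort(colnames(G)[ss])
      }
    }
    expect_equal(sel$selected, best_set)
  })
})

test_that("exhaustive selection tie-breaks duplicates lexicographically", {
  withr::with_seed(133, {
    n <- 200
    g <- rbinom(n, 2, 0.3)
    G <- cbind(sA = g, sB = g)  # identical causal columns
    y <- 1.5 * g + rnorm(n)
    sel <- exhaustive_selection(y, G)
    expect_equal(sel$selected, "sA")
  })
  expect_error(exhaustive_selection(rnorm(20), matrix(0, 20, 11)),
               "bound exceeded")
})
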