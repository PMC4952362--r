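# SNP-set construction and the self-contained permutation association tests.

# Fixture: an LD panel + cohort sharing SNPs, with best-eQTL rows for three
# genes, one of which sits in a configurable MHC-like region.
setassoc_fixture <- function(seed = 1, n_cases = 150, n_controls = 150,
                             disease_snps = NULL, ld_rho = 0.9) {
  sc <- sim_scenario(n_samples = 200, n_genes = 4, snps_per_gene_region = 5,
                     ld_block_size = 5, ld_rho = ld_rho,
                     maf_range = c(0.2, 0.4), n_cases = n_cases,
                     n_controls = n_controls, disease_snps = disease_snps)
  panel <- simulate_genotypes(sc, seed)
  cohort <- simulate_case_control(simulate_genotypes(sc, seed + 1), sc,
                                  seed + 2)
  genes <- scenario_gene_annotations(sc)
  best <- data.frame(
    gene_id = c("G001", "G002", "G003"),
    snp_id = c("G001_S03", "G002_S02", "G003_S04"),
    cell_type = "CD4", p = c(1e-8, 1e-6, 1e-4),
    fdr = c(0.001, 0.01, 0.05), significant = TRUE,
    stringsAsFactors = FALSE)
  list(sc = sc, panel = panel, cohort = cohort, genes = genes, best = best)
}

test_that("snp set construction tags, intersects, excludes MHC and filters", {
  fx <- setassoc_fixture(seed = 201)
  cfg <- small_config()
  sset <- build_snp_set(fx$best, fx$panel, fx$cohort, fx$genes, cfg)
  expect_s3_class(sset, "snp_set")
  expect_true(all(sset$members %in% fx$cohort$geno$snps$snp_id))
  # provenance carries index SNP and r2 at or above the threshold
  expect_true(all(sset$provenance$r2 >= cfg$r2_tag_min))
  expect_true(all(sset$audit$multiple_R[sset$audit$retained] <=
                    cfg$max_multiple_corr))
  # a gene placed inside the MHC region is excluded entirely
  genes_mhc <- fx$genes
  genes_mhc$chrom[genes_mhc$gene_id == "G001"] <- "chrM"
  cfg_mhc <- run_config(seed = 1, n_perms_eqtl = 60,
                        mhc_region = list(chrom = "chrM",
                                          start_bp = 1L,
                                          end_bp = 300000000L))
  sset2 <- build_snp_set(fx$best, fx$panel, fx$cohort, genes_mhc, cfg_mhc)
  expect_false("G001" %in% sset2$provenance$gene_id)
  expect_true("G002" %in% sset2$provenance$gene_id)
  # everything in the MHC -> error naming the step
  genes_all <- fx$genes
  genes_all$chrom <- "chrM"
  expect_error(build_snp_set(fx$best, fx$panel, fx$cohort, genes_all,
                             cfg_mhc), "MHC")
  expect_error(build_snp_set(fx$best[0, ], fx$panel, fx$cohort, fx$genes,
                             cfg), "no significant")
})

test_that("a proxy stands in when the index SNP is absent from the chip", {
  fx <- setassoc_fixture(seed = 202)
  cfg <- small_config()
  full <- build_snp_set(fx$best, fx$panel, fx$cohort, fx$genes, cfg)
  # find a proxy of the G001 index other than the index itself
  prov1 <- full$provenance[full$provenance$gene_id == "G001", ]
  expect_gt(nrow(prov1), 0)
  # drop the index SNP from the cohort chip
  keep <- setdiff(fx$cohort$geno$snps$snp_id, "G001_S03")
  cohort2 <- case_control_cohort(geno_subset(fx$cohort$geno, snps = keep),
                                 fx$cohort$phenotype)
  sset2 <- build_snp_set(fx$best, fx$panel, cohort2, fx$genes, cfg)
  prov2 <- sset2$provenance[sset2$provenance$gene_id == "G001", ]
  expect_false("G001_S03" %in% sset2$members)
  expect_gt(nrow(prov2), 0)                 # a proxy entered the set
  expect_true(all(prov2$r2 >= cfg$r2_tag_min))
})

test_that("duplicate proxies enter once but keep every provenance row", {
  fx <- setassoc_fixture(seed = 203)
  # make two genes share an index SNP by duplicating the best row
  best <- rbind(fx$best,
                data.frame(gene_id = "G004", snp_id = "G001_S03",
                           cell_type = "CD8", p = 1e-5, fdr = 0.02,
                           significant = TRUE, stringsAsFactors = FALSE))
  sset <- build_snp_set(best, fx$panel, fx$cohort, fx$genes, small_config())
  expect_equal(anyDuplicated(sset$members), 0)
  shared <- sset$provenance[sset$provenance$snp_id == "G001_S03", ]
  expect_setequal(shared$gene_id, c("G001", "G004"))
})

test_that("set association sums per-SNP allelic statistics exactly", {
  fx <- setassoc_fixture(seed = 204)
  coh <- fx$cohort
  one <- set_association(coh$geno$snps$snp_id[1], coh, n_perms = 50,
                         seed = 9)
  case <- coh$phenotype$case == 1
  direct <- allelic_chi2(coh$geno$dosage[case, 1],
                         coh$geno$dosage[!case, 1])
  expect_equal(one$sum_chi2, direct$chi2, tolerance = 1e-12)
  expect_equal(one$n_snps, 1L)
  # lambda identities on the result
  expect_equal(one$lambda_1000_set,
               lambda_1000(one$lambda_set, one$n_cases, one$n_controls))
})

test_that("set association is deterministic and order-invariant", {
  fx <- setassoc_fixture(seed = 205)
  snps <- fx$cohort$geno$snps$snp_id[1:10]
  a <- set_association(snps, fx$cohort, n_perms = 100, seed = 3)
  b <- set_association(snps, fx$cohort, n_perms = 100, seed = 3)
  expect_equal(a$empirical_p, b$empirical_p)
  expect_equal(a$sum_chi2, b$sum_chi2)
  # permuting the SNP order leaves the summed test untouched
  c_ <- set_association(rev(snps), fx$cohort, n_perms = 100, seed = 3)
  expect_equal(a$sum_chi2, c_$sum_chi2, tolerance = 1e-12)
  expect_equal(a$empirical_p, c_$empirical_p)
})

test_that("monomorphic SNPs are dropped, not fatal; p_report shows floor", {
  fx <- setassoc_fixture(seed = 206)
  d <- fx$cohort$geno$dosage
  d[, 1] <- 0  # zero ALT margin
  coh <- case_control_cohort(geno_matrix(d, fx$cohort$geno$snps),
                             fx$cohort$phenotype)
  snps <- coh$geno$snps$snp_id[1:5]
  res <- set_association(snps, coh, n_perms = 20, seed = 2)
  expect_equal(res$dropped_snps, snps[1])
  expect_equal(res$n_snps, 4L)
  # an observed sum above every permuted sum reports the "<1/B" string
  if (res$empirical_p == 0) expect_equal(res$p_report, paste0("<", 1 / 20))
})

test_that("planted disease SNPs push the empirical p down", {
  ds <- data.frame(snp = c("G001_S03", "G002_S02"), odds_ratio = 1.8,
                   stringsAsFactors = FALSE)
  fx <- setassoc_fixture(seed = 207, n_cases = 400, n_controls = 400,
                         disease_snps = ds)
  snps <- c("G001_S03", "G002_S02", "G003_S04", "G004_S01")
  res <- set_association(snps, fx$cohort, n_perms = 400, seed = 11)
  expect_lt(res$empirical_p, 0.05)
  expect_gt(res$lambda_set, 1)
})

test_that("gene-level association shares the set-level machinery", {
  fx <- setassoc_fixture(seed = 208)
  cfg <- small_config()
  sset <- build_snp_set(fx$best, fx$panel, fx$cohort, fx$genes, cfg)
  gres <- gene_level_association(sset, fx$cohort, n_perms = 100, seed = 7)
  expect_true(all(gres$status %in% c("ok", "no data")))
  ok <- gres[gres$status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$empirical_p >= 0 & ok$empirical_p <= 1))
  expect_equal(ok$bh_adjusted_p, bh_adjust(ok$empirical_p))
})

test_that("gene-level p equals set-level p for a one-gene set", {
  fx <- setassoc_fixture(seed = 209)
  cfg <- small_config()
  sset <- build_snp_set(fx$best, fx$panel, fx$cohort, fx$genes, cfg)
  g <- sset$provenance$gene_id[1]
  one <- sset
  one$provenance <- sset$provenance[sset$provenance$gene_id == g, ,
                                    drop = FALSE]
  gres <- gene_level_association(one, fx$cohort, n_perms = 150, seed = 13,
                                 max_R = cfg$max_multiple_corr)
  gres <- gres[gres$status == "ok", ]
  # reproduce the gene's filtered SNP list and run the set-level test
  prov <- one$provenance[order(one$provenance$index_p, -one$provenance$r2,
                               one$provenance$snp_id), ]
  cands <- unique(prov$snp_id)
  retained <- attr(independence_filter(cands, fx$cohort$geno,
                                       cfg$max_multiple_corr), "retained")
  sres <- set_association(retained, fx$cohort, n_perms = 150, seed = 13)
  expect_equal(gres$sum_chi2, sres$sum_chi2, tolerance = 1e-12)
  expect_equal(gres$empirical_p, sres$empirical_p)
  expect_equal(gres$bh_adjusted_p, gres$empirical_p)
})

test_that("gene length does not drive gene-level p under the null", {
  # genes of widely varying length, null cohort: Spearman correlation of
  # length with gene-level p stays near zero
  rhos <- vapply(1:5, function(s) {
    sc <- sim_scenario(n_samples = 200, n_genes = 12,
                       snps_per_gene_region = 4, ld_rho = 0.8,
                       maf_range = c(0.2, 0.4), n_cases = 100,
                       n_controls = 100)
    panel <- simulate_genotypes(sc, 500 + s)
    cohort <- simulate_case_control(simulate_genotypes(sc, 600 + s), sc,
                                    700 + s)
    genes <- scenario_gene_annotations(sc)
    # synthetic length spread (provenance grouping is what matters)
    genes$end_bp <- genes$start_bp + as.integer(seq(5000, 300000,
                                                    length.out = 12))
    best <- data.frame(gene_id = genes$gene_id,
                       snp_id = sprintf("%s_S02", genes$gene_id),
                       cell_type = "CD4",
                       p = rep(1e-6, 12), fdr = 0.01, significant = TRUE,
                       stringsAsFactors = FALSE)
    sset <- build_snp_set(best, panel, cohort, genes, small_config())
    gres <- gene_level_association(sset, cohort, n_perms = 100,
                                   seed = 800 + s)
    ok <- gres$status == "ok"
    len <- genes$end_bp[match(gres$gene_id[ok], genes$gene_id)] -
      genes$start_bp[match(gres$gene_id[ok], genes$gene_id)]
    spearman_rho(len, gres$empirical_p[ok])$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.3)
})

test_that("effect direction classification is allele-consistent", {
  expect_equal(classify_effect_direction(0.5, "ALT"),
               "risk-increases-expression")
  expect_equal(classify_effect_direction(0.5, "REF"),
               "risk-decreases-expression")
  # protective ALT allele with increased expression: risk (REF) decreases it
  expect_equal(classify_effect_direction(0.7, "REF"),
               "risk-decreases-expression")
  # invariance under simultaneous relabelling + sign flip
  expect_equal(classify_effect_direction(-0.5, "REF"),
               classify_effect_direction(0.5, "ALT"))
  expect_error(classify_effect_direction(0, "ALT"), "no direction")
  expect_error(classify_effect_direction(1, "X"), "REF")
})

test_that("catalog enrichment builds the 2x2 table and Fisher p", {
  # equal proportions -> no association
  expect_equal(catalog_enrichment(10, 40, 100, 400)$p, 1.0)
  # strong enrichment: p far below 1e-9 (hypergeometric tail)
  res <- catalog_enrichment(21, 88, 100, 20000)
  expect_lt(res$p, 1e-9)
  expect_gt(res$odds_ratio, 1)
  # doubling all counts sharpens, not weakens, the signal
  res2 <- catalog_enrichment(42, 176, 200, 40000)
  expect_lt(res2$p, res$p * 10)
  expect_error(catalog_enrichment(10, 5, 1, 10), "exceed")
})
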