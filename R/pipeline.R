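# Stage orchestration: simulate -> eqtl -> select -> setassoc -> chromatin,
# every stochastic step seeded deterministically from the single config seed,
# all artifacts exchanged as plain-text tables so stages compose across CLI
# invocations.

# Fixed per-stage seed offsets derived from the config seed; independent
# streams, reproducible runs.
.stage_seed <- function(config, stage) {
  off <- c(simulate = 101L, eqtl = 202L, select = 303L, setassoc = 404L,
           chromatin = 505L)
  (config$seed + off[[stage]]) %% (2^31 - 1)
}

.artifact <- function(out_dir, name) file.path(out_dir, name)

.require_artifact <- function(path, stage, producer) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' is missing its input artifact '",
         basename(path), "' (produced by the '", producer, "' stage or ",
         "supplied via config paths)")
  }
  path
}

# Resolve an input path: explicit config path wins, else the simulate-stage
# artifact in out_dir.
.input_path <- function(config, key, default_name) {
  p <- config$paths[[key]]
  if (!is.null(p) && nzchar(p)) p else .artifact(config$out_dir, default_name)
}

.stage_simulate <- function(config) {
  sc <- config$scenario
  if (is.null(sc)) stop("simulate stage requires a scenario in the config")
  seed <- .stage_seed(config, "simulate")
  out <- config$out_dir
  geno <- simulate_genotypes(sc, seed)
  covars <- simulate_covariates(sc, seed + 1L)
  genes <- scenario_gene_annotations(sc)
  cell_types <- if (!is.null(sc$eqtl_map)) unique(sc$eqtl_map$cell_type) else
    "CD4"
  write_genotypes_vcf(geno, .artifact(out, "genotypes.vcf"))
  write_covariates_tsv(covars, .artifact(out, "covariates.tsv"))
  write_gene_annotations_gff3(genes, .artifact(out, "genes.gff3"))
  for (i in seq_along(cell_types)) {
    ct <- cell_types[i]
    expr <- simulate_expression(geno, covars, sc, ct, seed + 10L + i)
    write_expression_tsv(expr, .artifact(out, paste0("expression_", ct,
                                                     ".tsv")))
  }
  cohort <- simulate_case_control(geno, sc, seed + 50L)
  write_genotypes_vcf(cohort$geno, .artifact(out, "cohort.vcf"))
  write_phenotype_tsv(cohort$phenotype, .artifact(out, "phenotype.tsv"))
  track <- simulate_coverage(geno, sc, seed + 60L)
  write_coverage_bed(track, .artifact(out, "coverage.bed"))
  manifest <- data.frame(kind = character(), gene = character(),
                         snp = character(), cell_type = character(),
                         value = numeric(), stringsAsFactors = FALSE)
  if (!is.null(sc$eqtl_map) && nrow(sc$eqtl_map) > 0) {
    manifest <- rbind(manifest, data.frame(
      kind = "eqtl_beta", gene = sc$eqtl_map$gene, snp = sc$eqtl_map$snp,
      cell_type = sc$eqtl_map$cell_type, value = sc$eqtl_map$beta,
      stringsAsFactors = FALSE))
  }
  if (!is.null(sc$disease_snps) && nrow(sc$disease_snps) > 0) {
    manifest <- rbind(manifest, data.frame(
      kind = "disease_or", gene = NA_character_, snp = sc$disease_snps$snp,
      cell_type = NA_character_, value = sc$disease_snps$odds_ratio,
      stringsAsFactors = FALSE))
  }
  write_result_tsv(manifest, .artifact(out, "manifest.tsv"))
  list(cell_types = cell_types, n_snps = ncol(geno$dosage),
       n_samples = nrow(geno$dosage), seed = seed)
}

.load_eqtl_inputs <- function(config, stage) {
  out <- config$out_dir
  vcf <- .require_artifact(.input_path(config, "genotypes_vcf",
                                       "genotypes.vcf"), stage, "simulate")
  cov <- .require_artifact(.input_path(config, "covariates_tsv",
                                       "covariates.tsv"), stage, "simulate")
  gff <- .require_artifact(.input_path(config, "genes_gff", "genes.gff3"),
                           stage, "simulate")
  geno <- load_genotypes_vcf(vcf)
  covars <- load_covariates_tsv(cov)
  genes <- load_gene_annotations(gff)
  expr_files <- if (!is.null(config$paths$expression_tsv)) {
    config$paths$expression_tsv
  } else {
    list.files(out, pattern = "^expression_.*\\.tsv$", full.names = TRUE)
  }
  if (length(expr_files) == 0) {
    stop("stage '", stage, "' found no expression_<celltype>.tsv artifacts")
  }
  cts <- sub("^expression_(.*)\\.tsv$", "\\1", basename(expr_files))
  exprs <- lapply(seq_along(expr_files), function(i) {
    load_expression_tsv(expr_files[i], cts[i])
  })
  list(geno = geno, covars = covars, genes = genes, exprs = exprs,
       cell_types = cts)
}

.stage_eqtl <- function(config) {
  seed <- .stage_seed(config, "eqtl")
  out <- config$out_dir
  inp <- .load_eqtl_inputs(config, "eqtl")
  tables <- list()
  for (i in seq_along(inp$exprs)) {
    tab <- map_cis_eqtls(inp$exprs[[i]], inp$geno, inp$covars, inp$genes,
                         config, seed + i)
    write_result_tsv(tab, .artifact(out, paste0("eqtl_", inp$cell_types[i],
                                                ".tsv")))
    tables[[i]] <- tab
  }
  all_tab <- do.call(rbind, tables)
  best <- best_snp_per_gene(all_tab)
  write_result_tsv(best, .artifact(out, "best_eqtl.tsv"))
  fm <- attr(best, "fdr_matrix")
  write_result_tsv(data.frame(gene_id = rownames(fm), fm,
                              check.names = FALSE),
                   .artifact(out, "best_eqtl_matrix.tsv"))
  # concordance of significant eQTL effects between the two status groups
  conc <- list()
  for (i in seq_along(inp$exprs)) {
    tab <- tables[[i]]
    if (any(tab$significant)) {
      conc[[length(conc) + 1]] <- subgroup_concordance(
        tab, inp$exprs[[i]], inp$geno, inp$covars, "status")
    }
  }
  conc <- if (length(conc) > 0) do.call(rbind, conc) else
    data.frame(gene_id = character(), snp_id = character())
  write_result_tsv(conc, .artifact(out, "concordance.tsv"))
  # exhaustive variable selection where a gene has multiple significant SNPs
  sel <- list()
  covar_cols <- setdiff(names(inp$covars), "sample")
  for (i in seq_along(inp$exprs)) {
    tab <- tables[[i]]
    expr <- inp$exprs[[i]]
    samples <- intersect(rownames(expr), geno_samples(inp$geno))
    samples <- intersect(samples, inp$covars$sample)
    Xc <- as.matrix(inp$covars[match(samples, inp$covars$sample),
                               covar_cols, drop = FALSE])
    sig <- tab[tab$significant, , drop = FALSE]
    for (g in unique(sig$gene_id)) {
      snps <- sort(sig$snp_id[sig$gene_id == g])
      if (length(snps) < 2) {
        n_sel <- length(snps); chosen <- snps
      } else {
        if (length(snps) > 10) {
          keep <- sig[sig$gene_id == g, , drop = FALSE]
          keep <- keep[order(keep$p, keep$snp_id), , drop = FALSE]
          snps <- sort(keep$snp_id[1:10])
        }
        res <- exhaustive_selection(
          unclass(expr)[samples, g],
          inp$geno$dosage[samples, snps, drop = FALSE], Xc)
        n_sel <- res$size; chosen <- res$selected
      }
      sel[[length(sel) + 1]] <- data.frame(
        gene_id = g, cell_type = inp$cell_types[i],
        n_candidates = length(snps), n_selected = n_sel,
        selected = paste(chosen, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  sel <- if (length(sel) > 0) do.call(rbind, sel) else
    data.frame(gene_id = character(), cell_type = character(),
               n_candidates = integer(), n_selected = integer(),
               selected = character())
  write_result_tsv(sel, .artifact(out, "selection_sizes.tsv"))
  list(n_rows = nrow(all_tab), n_significant = sum(all_tab$significant),
       n_genes_with_eqtl = length(unique(all_tab$gene_id[
        all_tab$significant])), seed = seed)
}

.load_cohort <- function(config, stage) {
  vcf <- .require_artifact(.input_path(config, "cohort_vcf", "cohort.vcf"),
                           stage, "simulate")
  phe <- .require_artifact(.input_path(config, "phenotype_tsv",
                                       "phenotype.tsv"), stage, "simulate")
  case_control_cohort(load_genotypes_vcf(vcf), load_phenotype_tsv(phe))
}

.stage_select <- function(config) {
  out <- config$out_dir
  best_path <- .require_artifact(.artifact(out, "best_eqtl.tsv"), "select",
                                 "eqtl")
  best <- read.table(best_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  inp <- .load_eqtl_inputs(config, "select")
  cohort <- .load_cohort(config, "select")
  sset <- build_snp_set(best, inp$geno, cohort, inp$genes, config)
  write_result_tsv(sset$provenance, .artifact(out, "tagsets.tsv"))
  write_result_tsv(sset$audit, .artifact(out, "independent_set.tsv"))
  prov <- sset$provenance
  mR <- sset$audit$multiple_R[match(prov$snp_id, sset$audit$snp_id)]
  write_result_tsv(cbind(prov, multiple_R = mR),
                   .artifact(out, "snp_set.tsv"))
  list(n_members = length(sset$members),
       n_genes = length(unique(prov$gene_id)))
}

# Rebuild a snp_set object from the select stage's artifacts.
.read_snp_set <- function(out_dir, stage) {
  prov_path <- .require_artifact(.artifact(out_dir, "snp_set.tsv"), stage,
                                 "select")
  audit_path <- .require_artifact(.artifact(out_dir, "independent_set.tsv"),
                                  stage, "select")
  prov <- read.table(prov_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  audit <- read.table(audit_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  members <- audit$snp_id[audit$retained]
  prov$multiple_R <- NULL
  structure(list(members = members, provenance = prov, audit = audit,
                 n_dropped_monomorphic = NA_integer_), class = "snp_set")
}

.stage_setassoc <- function(config) {
  seed <- .stage_seed(config, "setassoc")
  out <- config$out_dir
  sset <- .read_snp_set(out, "setassoc")
  cohort <- .load_cohort(config, "setassoc")
  # genome-wide reference: all polymorphic cohort SNPs, independence-filtered
  # in genomic order
  alt <- colSums(cohort$geno$dosage, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(cohort$geno$dosage))
  poly <- cohort$geno$snps$snp_id[alt > 0 & alt < n2]
  genome_ids <- attr(independence_filter(poly, cohort$geno,
                                         config$max_multiple_corr),
                     "retained")
  res <- set_association(sset, cohort, config$n_perms_set, seed,
                         genome_snps = genome_ids)
  write_result_tsv(data.frame(
    lambda_genome = res$lambda_genome, lambda_set = res$lambda_set,
    lambda_1000_set = res$lambda_1000_set, sum_chi2 = res$sum_chi2,
    empirical_p = res$empirical_p, p_report = res$p_report,
    n_perms = res$n_perms, n_snps = res$n_snps, n_cases = res$n_cases,
    n_controls = res$n_controls, seed = seed),
    .artifact(out, "set_assoc.tsv"))
  gene_res <- gene_level_association(sset, cohort, config$n_perms_set,
                                     seed + 1L, config$max_multiple_corr)
  write_result_tsv(gene_res, .artifact(out, "gene_assoc.tsv"))
  # qq coordinates (observed vs expected 1-df quantiles at (i - 0.5) / n)
  qq_tab <- function(chi2) {
    chi2 <- sort(chi2)
    n <- length(chi2)
    data.frame(expected = qchisq((seq_len(n) - 0.5) / n, df = 1),
               observed = chi2)
  }
  write_result_tsv(qq_tab(res$chi2_obs), .artifact(out, "qq_set.tsv"))
  gg <- .cohort_chi2(genome_ids, cohort, 1L, seed)
  write_result_tsv(qq_tab(gg$chi2_obs), .artifact(out, "qq_genome.tsv"))
  # risk-allele effect directions for set members
  best_path <- .artifact(out, "best_eqtl.tsv")
  dirs <- data.frame(gene_id = character(), snp_id = character(),
                     cell_type = character(), risk_allele = character(),
                     direction = character(), stringsAsFactors = FALSE)
  if (file.exists(best_path)) {
    best <- read.table(best_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    prov <- sset$provenance
    idx <- prov[prov$snp_id == prov$index_snp_id, , drop = FALSE]
    for (r in seq_len(nrow(idx))) {
      b <- best[best$gene_id == idx$gene_id[r] &
                  best$snp_id == idx$index_snp_id[r] &
                  best$cell_type == idx$cell_type[r], , drop = FALSE]
      if (nrow(b) == 0 || is.na(b$beta_all[1]) || b$beta_all[1] == 0) next
      d <- cohort$geno$dosage[, idx$snp_id[r]]
      case <- cohort$phenotype$case
      f_case <- mean(d[case == 1], na.rm = TRUE)
      f_ctrl <- mean(d[case == 0], na.rm = TRUE)
      risk <- if (f_case >= f_ctrl) "ALT" else "REF"
      dirs <- rbind(dirs, data.frame(
        gene_id = idx$gene_id[r], snp_id = idx$snp_id[r],
        cell_type = idx$cell_type[r], risk_allele = risk,
        direction = classify_effect_direction(b$beta_all[1], risk),
        stringsAsFactors = FALSE))
    }
  }
  write_result_tsv(dirs, .artifact(out, "directions.tsv"))
  list(empirical_p = res$empirical_p, lambda_set = res$lambda_set,
       lambda_genome = res$lambda_genome,
       lambda_1000_set = res$lambda_1000_set,
       n_genes_tested = sum(gene_res$status == "ok"), seed = seed)
}

.stage_chromatin <- function(config) {
  seed <- .stage_seed(config, "chromatin")
  out <- config$out_dir
  bed <- .require_artifact(.input_path(config, "coverage_bed",
                                       "coverage.bed"), "chromatin",
                           "simulate")
  track <- load_coverage_bed(bed)
  inp <- .load_eqtl_inputs(config, "chromatin")
  best_path <- .require_artifact(.artifact(out, "best_eqtl.tsv"),
                                 "chromatin", "eqtl")
  best <- read.table(best_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  pool <- inp$geno$snps
  cpm <- cpm_at_snps(track, pool)
  write_result_tsv(data.frame(snp_id = pool$snp_id, chrom = pool$chrom,
                              pos = pool$pos, cpm = cpm),
                   .artifact(out, "cpm_per_snp.tsv"))
  sig <- best[best$significant, , drop = FALSE]
  enr_rows <- list()
  if (nrow(sig) > 0) {
    sig_snps <- pool[match(unique(sig$snp_id), pool$snp_id), , drop = FALSE]
    # LD-expanded variant: eQTL SNPs plus their r2-threshold proxies
    proxies <- unique(unlist(lapply(unique(sig$snp_id), function(s) {
      tag_snps(s, inp$geno, config$r2_tag_min,
               config$tag_window_bp)$proxy_snp_id
    })))
    exp_snps <- pool[match(proxies, pool$snp_id), , drop = FALSE]
    enr <- sampling_null_enrichment(sig_snps, pool, track,
                                    n_iter = config$n_iter_null, seed = seed,
                                    expanded_snps = exp_snps)
    enr_rows[[1]] <- data.frame(
      set = "eqtl_snps", observed_mean_cpm = enr$observed_mean_cpm,
      null_mean = enr$null_mean, null_sd = enr$null_sd,
      empirical_p = enr$empirical_p, n_iter = enr$n_iter,
      n_snps = enr$n_snps, seed = seed, stringsAsFactors = FALSE)
    enr_rows[[2]] <- data.frame(
      set = "ld_expanded", observed_mean_cpm = enr$expanded$observed_mean_cpm,
      null_mean = enr$expanded$null_mean, null_sd = enr$expanded$null_sd,
      empirical_p = enr$expanded$empirical_p, n_iter = enr$expanded$n_iter,
      n_snps = enr$expanded$n_snps, seed = seed, stringsAsFactors = FALSE)
  }
  enr_tab <- if (length(enr_rows) > 0) do.call(rbind, enr_rows) else
    data.frame(set = character(), observed_mean_cpm = numeric())
  write_result_tsv(enr_tab, .artifact(out, "enrichment.tsv"))
  # strength vs acetylation per cell type on best rows regardless of FDR
  sva <- list()
  for (ct in unique(best$cell_type)) {
    rows <- best[best$cell_type == ct, , drop = FALSE]
    if (nrow(rows) < 3) next
    res <- tryCatch(strength_vs_acetylation(rows, track, pool),
                    error = function(e) NULL)
    if (!is.null(res)) {
      sva[[length(sva) + 1]] <- data.frame(cell_type = ct, rho = res$rho,
                                           p = res$p, n = res$n,
                                           stringsAsFactors = FALSE)
    }
  }
  sva <- if (length(sva) > 0) do.call(rbind, sva) else
    data.frame(cell_type = character(), rho = numeric(), p = numeric(),
               n = integer())
  write_result_tsv(sva, .artifact(out, "strength_vs_acetylation.tsv"))
  list(n_pool = nrow(pool), n_eqtl_snps = length(unique(sig$snp_id)),
       seed = seed)
}

#' Run the full pipeline (or a subset of stages)
#'
#' Executes the enabled stages in order `simulate`, `eqtl`, `select`,
#' `setassoc`, `chromatin`. Every stochastic step is seeded deterministically
#' from `config$seed` with fixed per-stage offsets, so re-running the same
#' config reproduces every result table byte for byte. Stage dependencies
#' are enforced through their file artifacts: a missing input artifact is an
#' error naming the artifact and the stage that produces it.
#'
#' @param config a [run_config()]; `config$stages` selects the stages.
#' @return the run report (named list per stage: row counts, seeds, key
#'   results), invisibly; also written to `report.yaml` in the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 thresholds = list(
                   maf_min = config$maf_min,
                   eqtl_fdr_threshold = config$eqtl_fdr_threshold,
                   r2_tag_min = config$r2_tag_min,
                   max_multiple_corr = config$max_multiple_corr))
  runners <- list(simulate = .stage_simulate, eqtl = .stage_eqtl,
                  select = .stage_select, setassoc = .stage_setassoc,
                  chromatin = .stage_chromatin)
  for (stage in c("simulate", "eqtl", "select", "setassoc", "chromatin")) {
    if (stage %in% config$stages) {
      report[[stage]] <- runners[[stage]](config)
    }
  }
  yaml::write_yaml(report, .artifact(config$out_dir, "report.yaml"))
  invisible(report)
}

#' The shipped demonstration scenario
#'
#' A compact end-to-end scenario used by the README worked example and the
#' package's reproduction script: 12 genes with 5 cis SNPs each in strong LD
#' blocks, two cell types, six planted eQTLs of moderate effect, two of the
#' eQTL SNPs carrying disease odds ratios of 1.4, a 600-case / 600-control
#' cohort and a coverage track with peaks at the planted eQTL SNPs.
#'
#' @return a [sim_scenario()].
#' @export
demo_scenario <- function() {
  sim_scenario(
    n_samples = 200L, n_genes = 12L, snps_per_gene_region = 5L,
    maf_range = c(0.1, 0.4), ld_block_size = 5L, ld_rho = 0.8,
    eqtl_map = data.frame(
      gene = sprintf("G%03d", 1:6),
      snp = sprintf("G%03d_S%02d", 1:6, c(3, 2, 4, 1, 5, 3)),
      cell_type = rep(c("CD4", "CD14"), 3),
      beta = c(1.2, 1.0, 0.9, 1.1, 0.8, 1.0),
      stringsAsFactors = FALSE),
    noise_sd = 1, n_cases = 600L, n_controls = 600L,
    disease_snps = data.frame(snp = c("G001_S03", "G004_S01"),
                              odds_ratio = c(1.4, 1.4),
                              stringsAsFactors = FALSE),
    peak_snps = c("G001_S03", "G002_S02", "G004_S01"),
    library_size = 200000L)
}
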