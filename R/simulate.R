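# Synthetic cohort generator. Produces genotype matrices with LD block
# structure, covariates, expression with planted additive genotype effects,
# logistic case-control phenotypes and coverage tracks with localized peaks,
# so that every analysis stage can be exercised end-to-end without access to
# the managed cohort data the method was designed for.

#' Define a simulation scenario
#'
#' Collects every knob of the synthetic cohorts: cohort and gene-region
#' sizes, the allele-frequency spectrum and LD block structure, the planted
#' expression effects (`eqtl_map`), covariate effects and noise, the logistic
#' disease model (`disease_snps` odds ratios and case/control counts) and the
#' coverage-track layout.
#'
#' Gene/SNP layout is deterministic: gene `i` is `G00i` spanning
#' `gene_span_bp` starting at `500000 + (i-1)*gene_spacing_bp` on `chrom`;
#' its `snps_per_gene_region` SNPs are `G00i_S01`, ... placed evenly across
#' the gene span plus 80 kbp flanks (inside the default 100 kbp cis window).
#'
#' @param n_samples samples in the expression/genotype cohort (default 200).
#' @param n_genes genes in the network (default 50).
#' @param snps_per_gene_region SNPs per gene cis region (default 5).
#' @param maf_range length-2 allele-frequency range, `0 < lo <= hi < 0.5`
#'   (default c(0.05, 0.45)). One frequency per LD block is drawn uniformly
#'   from this range and shared by the block's SNPs, so marginal MAF respects
#'   the range exactly.
#' @param ld_block_size SNPs per LD block (default 5).
#' @param ld_rho haplotype copying probability within a block, in \[0, 1)
#'   (default 0.8).
#' @param eqtl_map data.frame with columns `gene`, `snp`, `cell_type`,
#'   `beta` (expression units per ALT allele); genes absent from the map
#'   have no genotype effect. Default: none.
#' @param covariate_effects named numeric vector of slopes for columns of
#'   the covariate table (default status 0.5, sex 0.3, age 0.01, batch 0.2).
#' @param noise_sd expression noise SD (default 1).
#' @param disease_snps data.frame with columns `snp`, `odds_ratio`
#'   (default: none, a null disease model).
#' @param n_cases,n_controls case-control cohort sizes (default 1000 each).
#' @param peak_snps SNP ids receiving coverage peaks (default none).
#' @param library_size total reads in the coverage track (default 100000).
#' @param chrom chromosome label for the layout (default "chr1").
#' @param gene_span_bp,gene_spacing_bp gene length and inter-gene spacing
#'   (defaults 20 kbp and 1 Mbp, keeping cis windows disjoint).
#' @param read_length,peak_sd,peak_fraction coverage-read length (100 bp),
#'   SD of read placement around a peak SNP (200 bp) and the fraction of the
#'   library assigned to peaks when any are defined (0.5).
#' @param expr_intercept baseline expression level (default 8, a typical
#'   log2 microarray intensity).
#' @param freq_seed seed fixing the population's block allele frequencies.
#'   The frequencies are a property of the simulated population, not of a
#'   cohort draw: every genotype sample generated from the same scenario
#'   shares them, so pooled cohorts are free of artificial stratification.
#' @return a validated list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_samples = 200L, n_genes = 50L,
                         snps_per_gene_region = 5L,
                         maf_range = c(0.05, 0.45), ld_block_size = 5L,
                         ld_rho = 0.8, eqtl_map = NULL,
                         covariate_effects = c(status = 0.5, sex = 0.3,
                                               age = 0.01, batch = 0.2),
                         noise_sd = 1, disease_snps = NULL,
                         n_cases = 1000L, n_controls = 1000L,
                         peak_snps = character(0), library_size = 100000L,
                         chrom = "chr1", gene_span_bp = 20000L,
                         gene_spacing_bp = 1000000L, read_length = 100L,
                         peak_sd = 200, peak_fraction = 0.5,
                         expr_intercept = 8, freq_seed = 1979L) {
  sc <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
             snps_per_gene_region = as.integer(snps_per_gene_region),
             maf_range = as.numeric(maf_range),
             ld_block_size = as.integer(ld_block_size),
             ld_rho = as.numeric(ld_rho), eqtl_map = eqtl_map,
             covariate_effects = unlist(covariate_effects),
             noise_sd = as.numeric(noise_sd), disease_snps = disease_snps,
             n_cases = as.integer(n_cases),
             n_controls = as.integer(n_controls),
             peak_snps = as.character(unlist(peak_snps)),
             library_size = as.integer(library_size),
             chrom = as.character(chrom),
             gene_span_bp = as.integer(gene_span_bp),
             gene_spacing_bp = as.integer(gene_spacing_bp),
             read_length = as.integer(read_length),
             peak_sd = as.numeric(peak_sd),
             peak_fraction = as.numeric(peak_fraction),
             expr_intercept = as.numeric(expr_intercept),
             freq_seed = as.integer(freq_seed))
  if (sc$n_samples < 2) stop("n_samples must be >= 2")
  if (sc$n_genes < 1 || sc$snps_per_gene_region < 1) {
    stop("n_genes and snps_per_gene_region must be >= 1")
  }
  if (length(sc$maf_range) != 2 || sc$maf_range[1] <= 0 ||
      sc$maf_range[1] > sc$maf_range[2] || sc$maf_range[2] >= 0.5) {
    stop("maf_range must satisfy 0 < lo <= hi < 0.5")
  }
  if (sc$ld_rho < 0 || sc$ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (sc$n_cases < 1 || sc$n_controls < 1) {
    stop("n_cases and n_controls must be >= 1")
  }
  if (!is.null(sc$eqtl_map)) {
    sc$eqtl_map <- as.data.frame(sc$eqtl_map, stringsAsFactors = FALSE)
    if (!all(c("gene", "snp", "cell_type", "beta") %in%
               names(sc$eqtl_map))) {
      stop("eqtl_map needs columns gene, snp, cell_type, beta")
    }
  }
  if (!is.null(sc$disease_snps)) {
    sc$disease_snps <- as.data.frame(sc$disease_snps,
                                     stringsAsFactors = FALSE)
    if (!all(c("snp", "odds_ratio") %in% names(sc$disease_snps))) {
      stop("disease_snps needs columns snp, odds_ratio")
    }
    if (any(sc$disease_snps$odds_ratio <= 0)) {
      stop("odds ratios must be positive")
    }
  }
  if (sc$library_size < 1) stop("library_size must be >= 1")
  structure(sc, class = "sim_scenario")
}

#' Deterministic gene annotations of a scenario
#' @param scenario a [sim_scenario()].
#' @return a [gene_annotation()] table.
#' @export
scenario_gene_annotations <- function(scenario) {
  i <- seq_len(scenario$n_genes)
  start <- 500000L + (i - 1L) * scenario$gene_spacing_bp
  gene_annotation(sprintf("G%03d", i), scenario$chrom, start,
                  start + scenario$gene_span_bp - 1L)
}

# SNP metadata implied by the scenario layout: snps_per_gene_region SNPs per
# gene, evenly spaced over the gene span plus 80 kbp flanks.
.scenario_snp_meta <- function(scenario) {
  genes <- scenario_gene_annotations(scenario)
  k <- scenario$snps_per_gene_region
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    lo <- genes$start_bp[i] - 80000L
    hi <- genes$end_bp[i] + 80000L
    pos <- as.integer(round(seq(max(1, lo), hi, length.out = k)))
    pos <- pos + seq_len(k) - 1L  # guarantee distinct positions
    data.frame(snp_id = sprintf("%s_S%02d", genes$gene_id[i], seq_len(k)),
               chrom = genes$chrom[i], pos = pos, ref = "A", alt = "G",
               gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate genotypes with LD block structure
#'
#' For each LD block (consecutive runs of `ld_block_size` SNPs within a gene
#' region) a block allele frequency is drawn uniformly from `maf_range` and
#' `2 * n_samples` haplotypes are generated by a copying model: the first
#' SNP's allele is Bernoulli(freq) and each subsequent allele copies its
#' left neighbour with probability `ld_rho`, else is drawn fresh. Haplotype
#' pairs are summed into dosages. With `ld_rho = 0` SNPs are independent;
#' large `ld_rho` gives strong within-block dosage correlation.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return a [geno_matrix()] whose `snps` metadata carries a `gene_id`
#'   column with the source gene of each SNP's region.
#' @export
simulate_genotypes <- function(scenario, seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  meta <- .scenario_snp_meta(scenario)
  n <- scenario$n_samples
  nh <- 2L * n
  k <- scenario$snps_per_gene_region
  bs <- scenario$ld_block_size
  rho <- scenario$ld_rho
  # population block frequencies: fixed by the scenario, shared by every
  # cohort drawn from it (prevents stratification across pooled draws)
  n_blocks_per_gene <- ceiling(k / bs)
  freqs <- withr::with_seed(scenario$freq_seed, {
    runif(scenario$n_genes * n_blocks_per_gene, scenario$maf_range[1],
          scenario$maf_range[2])
  })
  withr::with_seed(seed, {
    dos <- matrix(0, nrow = n, ncol = nrow(meta))
    col <- 0L
    blk_i <- 0L
    for (g in seq_len(scenario$n_genes)) {
      blocks <- split(seq_len(k), ceiling(seq_len(k) / bs))
      for (blk in blocks) {
        blk_i <- blk_i + 1L
        p <- freqs[blk_i]
        H <- matrix(0L, nrow = nh, ncol = length(blk))
        H[, 1] <- rbinom(nh, 1, p)
        if (length(blk) > 1) {
          for (j in 2:length(blk)) {
            copy <- runif(nh) < rho
            fresh <- rbinom(nh, 1, p)
            H[, j] <- ifelse(copy, H[, j - 1], fresh)
          }
        }
        D <- H[seq(1, nh, by = 2), , drop = FALSE] +
          H[seq(2, nh, by = 2), , drop = FALSE]
        dos[, col + seq_along(blk)] <- D
        col <- col + length(blk)
      }
    }
    rownames(dos) <- sprintf("S%04d", seq_len(n))
    geno_matrix(dos, meta)
  })
}

#' Simulate a per-sample covariate table
#'
#' Columns: `sample`, `status` (0/1, balanced), `sex` (0/1), `age`
#' (uniform 20-70), `batch` (1/2).
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @return data.frame.
#' @export
simulate_covariates <- function(scenario, seed) {
  n <- scenario$n_samples
  withr::with_seed(seed, {
    data.frame(sample = sprintf("S%04d", seq_len(n)),
               status = rbinom(n, 1, 0.5), sex = rbinom(n, 1, 0.5),
               age = round(runif(n, 20, 70)),
               batch = sample(c(1L, 2L), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a normalized expression matrix
#'
#' `expression(gene, sample) = intercept + sum(covariate effects) +
#' beta * dosage + Normal(0, noise_sd)`, where `beta` comes from the
#' scenario's `eqtl_map` rows matching this `cell_type` (genes without a map
#' entry have no genotype effect).
#'
#' @param genotypes a [geno_matrix()] from [simulate_genotypes()].
#' @param covariates covariate table from [simulate_covariates()] (same
#'   samples).
#' @param scenario a [sim_scenario()].
#' @param cell_type label of the cell subset being simulated.
#' @param seed integer seed.
#' @return an [expr_matrix()] (samples x genes).
#' @export
simulate_expression <- function(genotypes, covariates, scenario, cell_type,
                                seed) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  genes <- scenario_gene_annotations(scenario)
  samples <- geno_samples(genotypes)
  if (!identical(sort(samples), sort(covariates$sample))) {
    stop("covariate samples do not match genotype samples")
  }
  covariates <- covariates[match(samples, covariates$sample), ]
  eff <- scenario$covariate_effects
  base <- rep(scenario$expr_intercept, length(samples))
  for (nm in names(eff)) {
    if (!nm %in% names(covariates)) {
      stop("covariate_effects names a missing covariate column: ", nm)
    }
    base <- base + eff[[nm]] * as.numeric(covariates[[nm]])
  }
  emap <- scenario$eqtl_map
  if (!is.null(emap)) {
    emap <- emap[emap$cell_type == cell_type, , drop = FALSE]
    bad_g <- setdiff(emap$gene, genes$gene_id)
    if (length(bad_g) > 0) stop("eqtl_map gene not in scenario: ", bad_g[1])
    bad_s <- setdiff(emap$snp, genotypes$snps$snp_id)
    if (length(bad_s) > 0) stop("eqtl_map SNP not in genotypes: ", bad_s[1])
  }
  withr::with_seed(seed, {
    m <- matrix(rnorm(length(samples) * nrow(genes), 0, scenario$noise_sd),
                nrow = length(samples), ncol = nrow(genes),
                dimnames = list(samples, genes$gene_id))
    m <- m + base
    if (!is.null(emap) && nrow(emap) > 0) {
      for (r in seq_len(nrow(emap))) {
        d <- genotypes$dosage[, emap$snp[r]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        m[, emap$gene[r]] <- m[, emap$gene[r]] + emap$beta[r] * d
      }
    }
    expr_matrix(m, cell_type)
  })
}

#' Simulate a case-control cohort from a logistic disease model
#'
#' Per-sample disease probability follows
#' `logit(p) = alpha + sum(log(OR) * dosage)` over the scenario's
#' `disease_snps`; `alpha` is tuned by bisection so the expected case
#' fraction matches `n_cases / (n_cases + n_controls)`. Case and control
#' quotas are filled by drawing disease status over the supplied genotype
#' pool, regenerating fresh genotype pools from the scenario (with new
#' derived seeds) whenever a quota is unmet, until exactly `n_cases` cases
#' and `n_controls` controls are collected.
#'
#' @param genotypes a [geno_matrix()] used as the first sampling pool.
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @return a [case_control_cohort()].
#' @export
simulate_case_control <- function(genotypes, scenario, seed) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  ds <- scenario$disease_snps
  if (!is.null(ds)) {
    miss <- setdiff(ds$snp, genotypes$snps$snp_id)
    if (length(miss) > 0) {
      stop("disease SNP absent from genotypes: ", paste(miss, collapse = ", "))
    }
  }
  target <- scenario$n_cases / (scenario$n_cases + scenario$n_controls)
  eta_of <- function(geno) {
    s <- rep(0, nrow(geno$dosage))
    if (!is.null(ds)) {
      for (r in seq_len(nrow(ds))) {
        d <- geno$dosage[, ds$snp[r]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        s <- s + log(ds$odds_ratio[r]) * d
      }
    }
    s
  }
  s0 <- eta_of(genotypes)
  f <- function(alpha) mean(stats::plogis(alpha + s0)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("cannot attain target case fraction")
  alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root

  max_pools <- ceiling(4 * (scenario$n_cases + scenario$n_controls) /
                         nrow(genotypes$dosage)) + 50L
  withr::with_seed(seed, {
    pool_seeds <- sample.int(2^31 - 2, max_pools)
    case_rows <- list(); ctrl_rows <- list()
    n_case <- 0L; n_ctrl <- 0L
    pool <- genotypes
    for (it in seq_len(max_pools)) {
      eta <- alpha + eta_of(pool)
      case <- rbinom(length(eta), 1, stats::plogis(eta))
      d <- pool$dosage
      rownames(d) <- sprintf("P%03d_%s", it, rownames(d))
      need_case <- scenario$n_cases - n_case
      need_ctrl <- scenario$n_controls - n_ctrl
      ci <- which(case == 1)[seq_len(min(need_case, sum(case == 1)))]
      ki <- which(case == 0)[seq_len(min(need_ctrl, sum(case == 0)))]
      if (length(ci) > 0) {
        case_rows[[length(case_rows) + 1]] <- d[ci, , drop = FALSE]
        n_case <- n_case + length(ci)
      }
      if (length(ki) > 0) {
        ctrl_rows[[length(ctrl_rows) + 1]] <- d[ki, , drop = FALSE]
        n_ctrl <- n_ctrl + length(ki)
      }
      if (n_case >= scenario$n_cases && n_ctrl >= scenario$n_controls) break
      pool <- simulate_genotypes(scenario, pool_seeds[it])
    }
    if (n_case < scenario$n_cases || n_ctrl < scenario$n_controls) {
      stop("unattainable case/control counts after ", max_pools,
           " genotype pools")
    }
    dosage <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
    phen <- data.frame(sample = rownames(dosage),
                       case = rep(c(1L, 0L),
                                  c(scenario$n_cases, scenario$n_controls)),
                       stringsAsFactors = FALSE)
    case_control_cohort(geno_matrix(dosage, genotypes$snps), phen)
  })
}

#' Simulate a coverage track with localized peaks
#'
#' Places `library_size` reads of length `read_length`: a background fraction
#' uniformly across the SNP-bearing region and, if `peak_snps` are defined,
#' `peak_fraction` of the library normally distributed (SD `peak_sd`) around
#' the peak SNP positions. Reads are aggregated into intervals with counts;
#' the summed count equals the library size exactly.
#'
#' @param snps SNP metadata (data.frame with `snp_id`, `chrom`, `pos`) or a
#'   [geno_matrix()].
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @return a [coverage_track()].
#' @export
simulate_coverage <- function(snps, scenario, seed) {
  if (inherits(snps, "geno_matrix")) snps <- snps$snps
  peaks <- scenario$peak_snps
  miss <- setdiff(peaks, snps$snp_id)
  if (length(miss) > 0) {
    stop("peak SNP absent from SNP list: ", paste(miss, collapse = ", "))
  }
  L <- scenario$read_length
  lo <- min(snps$pos) - 10000L
  hi <- max(snps$pos) + 10000L
  chrom <- snps$chrom[1]
  n_reads <- scenario$library_size
  n_peak <- if (length(peaks) > 0) {
    round(scenario$peak_fraction * n_reads)
  } else 0L
  n_bg <- n_reads - n_peak
  withr::with_seed(seed, {
    starts <- integer(0)
    if (n_bg > 0) {
      starts <- c(starts, as.integer(floor(runif(n_bg, lo, hi - L + 1))))
    }
    if (n_peak > 0) {
      centre <- snps$pos[match(peaks, snps$snp_id)]
      which_peak <- sample(seq_along(centre), n_peak, replace = TRUE)
      ps <- as.integer(round(rnorm(n_peak, centre[which_peak] - L / 2,
                                   scenario$peak_sd)))
      starts <- c(starts, pmin(pmax(ps, lo), hi - L + 1L))
    }
    tab <- table(starts)
    st <- as.integer(names(tab))
    coverage_track(data.frame(chrom = chrom, start = st, end = st + L - 1L,
                              count = as.numeric(tab),
                              stringsAsFactors = FALSE),
                   total_count = n_reads)
  })
}
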