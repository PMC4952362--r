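# SNP-set construction and self-contained disease association: LD-tagged,
# chip-intersected, MHC-excluded, independence-filtered eQTL SNP set;
# phenotype-permutation sum-of-chi-squared tests at set and gene level;
# effect-direction classification; catalog enrichment.

# Per-SNP allelic chi-squared statistics for one or many case indicator
# vectors, vectorised over SNPs x permutations. D is a complete (no NA)
# dosage matrix (samples x SNPs); Z a 0/1 matrix (samples x B) of case
# indicators with a constant column sum (phenotype permutations).
.allelic_chi2_matrix <- function(D, Z) {
  n <- nrow(D)
  n_case <- sum(Z[, 1])
  n_ctrl <- n - n_case
  alt_tot <- colSums(D)
  A <- crossprod(D, Z)                      # ALT alleles in cases, M x B
  Bm <- 2 * n_case - A                      # REF alleles in cases
  Cm <- alt_tot - A                         # ALT alleles in controls
  Dm <- 2 * n_ctrl - Cm                     # REF alleles in controls
  N <- 2 * n
  r1 <- 2 * n_case; r2 <- 2 * n_ctrl
  c1 <- alt_tot; c2 <- N - alt_tot
  num <- (A * Dm - Bm * Cm)^2
  N * num / (r1 * r2 * outer(c1 * c2, rep(1, ncol(Z))))
}

#' Build the eQTL SNP set for disease association testing
#'
#' Pipeline: each significant best-eQTL index SNP is expanded to its LD
#' proxies at `r2_tag_min` (inclusive) in the LD panel; proxies are
#' intersected with the SNPs typed in the case-control cohort; SNPs whose
#' source gene overlaps the configured MHC region are removed (long-range
#' MHC LD would confound disease association); the remainder is filtered for
#' relative independence (multiple correlation at most `max_multiple_corr`)
#' in the cohort genotypes, scanning in order of index-eQTL significance.
#' Per-SNP provenance (source gene, cell type, index SNP, r2 to index) is
#' retained for gene-level analysis; a SNP tagging several genes enters the
#' set once but keeps every provenance row.
#'
#' @param best_eqtls data.frame of significant best-eQTL rows with columns
#'   `gene_id`, `snp_id`, `cell_type`, `p` (rows with a `significant` column
#'   are restricted to `significant == TRUE`).
#' @param ld_panel a [geno_matrix()] used for proxy tagging.
#' @param cohort a [case_control_cohort()] whose chip defines the available
#'   SNPs and whose genotypes drive the independence filter.
#' @param genes a [gene_annotation()] table (for the MHC overlap rule).
#' @param config a [run_config()] (uses `r2_tag_min`, `tag_window_bp`,
#'   `mhc_region`, `max_multiple_corr`).
#' @return an object of class `snp_set`: list with `members`, `provenance`,
#'   `audit` (the independence-filter trace) and `n_dropped_monomorphic`.
#' @export
build_snp_set <- function(best_eqtls, ld_panel, cohort, genes, config) {
  if ("significant" %in% names(best_eqtls)) {
    best_eqtls <- best_eqtls[best_eqtls$significant, , drop = FALSE]
  }
  if (nrow(best_eqtls) == 0) {
    stop("no testable SNPs: no significant eQTL rows supplied")
  }
  # MHC rule: drop index eQTLs whose source gene overlaps the region
  m <- config$mhc_region
  g <- genes[match(best_eqtls$gene_id, genes$gene_id), , drop = FALSE]
  in_mhc <- !is.na(g$chrom) & g$chrom == m$chrom &
    g$start_bp <= m$end_bp & g$end_bp >= m$start_bp
  best_eqtls <- best_eqtls[!in_mhc, , drop = FALSE]
  if (nrow(best_eqtls) == 0) {
    stop("no testable SNPs: all source genes overlap the MHC region")
  }
  prov <- list()
  for (r in seq_len(nrow(best_eqtls))) {
    tags <- tryCatch(
      tag_snps(best_eqtls$snp_id[r], ld_panel, config$r2_tag_min,
               config$tag_window_bp),
      error = function(e) NULL
    )
    if (is.null(tags) || nrow(tags) == 0) next
    prov[[length(prov) + 1]] <- data.frame(
      snp_id = tags$proxy_snp_id, gene_id = best_eqtls$gene_id[r],
      cell_type = best_eqtls$cell_type[r],
      index_snp_id = best_eqtls$snp_id[r], r2 = tags$r2,
      index_p = best_eqtls$p[r], stringsAsFactors = FALSE)
  }
  if (length(prov) == 0) stop("no testable SNPs: LD tagging found no proxies")
  prov <- do.call(rbind, prov)
  cohort_ids <- cohort$geno$snps$snp_id
  prov <- prov[prov$snp_id %in% cohort_ids, , drop = FALSE]
  if (nrow(prov) == 0) {
    stop("no testable SNPs: no proxy present on the cohort chip")
  }
  # candidate order: index-eQTL significance, then proxy r2, then id
  ord <- order(prov$index_p, -prov$r2, prov$snp_id)
  cands <- unique(prov$snp_id[ord])
  D <- cohort$geno$dosage[, cands, drop = FALSE]
  mono <- vapply(seq_along(cands), function(j) {
    v <- D[, j]; v <- v[!is.na(v)]
    length(unique(v)) < 2
  }, logical(1))
  n_mono <- sum(mono)
  cands <- cands[!mono]
  if (length(cands) == 0) {
    stop("no testable SNPs: all candidates monomorphic in the cohort")
  }
  audit <- independence_filter(cands, cohort$geno, config$max_multiple_corr)
  members <- attr(audit, "retained")
  prov <- prov[prov$snp_id %in% members, , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(members = members, provenance = prov, audit = audit,
                 n_dropped_monomorphic = n_mono),
            class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat("snp_set:", length(x$members), "SNPs tagging",
      length(unique(x$provenance$gene_id)), "genes\n")
  invisible(x)
}

# Shared engine: observed + permuted per-SNP allelic chi2 for a member list.
# Returns list(chi2_obs = vector, chi2_perm = matrix M x B, members).
.cohort_chi2 <- function(members, cohort, n_perms, seed) {
  miss <- setdiff(members, cohort$geno$snps$snp_id)
  if (length(miss) > 0) {
    stop("set members absent from cohort genotypes: ",
         paste(miss, collapse = ", "))
  }
  case <- cohort$phenotype$case
  if (sum(case == 1) < 1 || sum(case == 0) < 1) {
    stop("cohort needs at least one case and one control")
  }
  D <- cohort$geno$dosage[, members, drop = FALSE]
  if (anyNA(D)) {
    # per-SNP mean imputation keeps allele totals permutation-invariant;
    # missingness is rare in the synthetic cohorts this package targets
    for (j in seq_len(ncol(D))) {
      v <- D[, j]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      D[, j] <- v
    }
  }
  # zero-margin (monomorphic) SNPs are permutation-invariant: drop once
  alt_tot <- colSums(D)
  ok <- alt_tot > 0 & alt_tot < 2 * nrow(D)
  dropped <- members[!ok]
  members <- members[ok]
  D <- D[, ok, drop = FALSE]
  if (length(members) == 0) stop("no polymorphic set members in cohort")
  perm_idx <- withr::with_seed(seed, {
    replicate(n_perms, sample(case))
  })
  Z <- cbind(case, perm_idx)
  res <- .allelic_chi2_matrix(D, Z)
  list(chi2_obs = res[, 1], chi2_perm = res[, -1, drop = FALSE],
       members = members, dropped = dropped)
}

#' Self-contained SNP-set disease association test
#'
#' Computes allelic chi-squared statistics for every set member, sums them,
#' permutes the case-control phenotype labels `n_perms` times (leaving the
#' genotype matrix, hence inter-SNP correlation, untouched), and reports the
#' empirical p value as the fraction of permuted sums strictly greater than
#' the observed sum. Also reports the genomic-control inflation of the set
#' statistics (`lambda_set`), its rescaling to a 1000/1000 cohort
#' (`lambda_1000_set`) and, when `genome_snps` is supplied (an
#' independence-filtered genome-wide SNP id list), the genome-wide inflation
#' `lambda_genome`.
#'
#' @param snp_set a [build_snp_set()] result, or a character vector of SNP
#'   ids.
#' @param cohort a [case_control_cohort()].
#' @param n_perms number of phenotype permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param genome_snps optional ids of independence-filtered genome-wide SNPs
#'   for the lambda comparison.
#' @return list of class `set_assoc_result`: `sum_chi2`, `n_perms`,
#'   `empirical_p` (with `conservative` attribute), `p_report` (the printed
#'   form, `"<1/n_perms"` when the raw fraction is zero), `lambda_set`,
#'   `lambda_genome`, `lambda_1000_set`, `n_cases`, `n_controls`, `n_snps`,
#'   `dropped_snps`, `seed`, and `chi2_obs` (per-SNP statistics).
#' @export
set_association <- function(snp_set, cohort, n_perms = 10000L, seed = 1L,
                            genome_snps = NULL) {
  if (n_perms < 1) stop("n_perms must be >= 1")
  members <- if (inherits(snp_set, "snp_set")) snp_set$members else
    as.character(snp_set)
  if (length(members) == 0) stop("empty SNP set")
  cc <- .cohort_chi2(members, cohort, n_perms, seed)
  sum_obs <- sum(cc$chi2_obs)
  sums_perm <- colSums(cc$chi2_perm)
  p <- empirical_p(sum_obs, sums_perm)
  lam_set <- genomic_inflation(cc$chi2_obs)
  n_cases <- sum(cohort$phenotype$case == 1)
  n_controls <- sum(cohort$phenotype$case == 0)
  lam_genome <- NA_real_
  if (!is.null(genome_snps)) {
    gg <- .cohort_chi2(genome_snps, cohort, 1L, seed)
    lam_genome <- genomic_inflation(gg$chi2_obs)
  }
  structure(list(
    sum_chi2 = sum_obs, n_perms = as.integer(n_perms),
    empirical_p = as.numeric(p),
    empirical_p_conservative = attr(p, "conservative"),
    p_report = if (as.numeric(p) == 0) paste0("<", format(1 / n_perms)) else
      format(as.numeric(p)),
    lambda_set = lam_set, lambda_genome = lam_genome,
    lambda_1000_set = lambda_1000(lam_set, n_cases, n_controls),
    n_cases = n_cases, n_controls = n_controls,
    n_snps = length(cc$members), dropped_snps = cc$dropped,
    seed = seed, chi2_obs = setNames(cc$chi2_obs, cc$members)
  ), class = "set_assoc_result")
}

#' @export
print.set_assoc_result <- function(x, ...) {
  cat("set_assoc_result:", x$n_snps, "SNPs, sum chi2 =",
      signif(x$sum_chi2, 5), "\n  empirical p =", x$p_report,
      "(", x$n_perms, "permutations )\n  lambda_set =",
      signif(x$lambda_set, 4), " lambda_1000 =",
      signif(x$lambda_1000_set, 4), "\n")
  invisible(x)
}

#' Gene-level disease association from eQTL SNP provenance
#'
#' Groups the SNP set by source gene, independently re-filters each gene's
#' SNP subset for relative independence, and computes the same
#' sum-of-chi-squared phenotype-permutation test per gene. One shared
#' permutation stream serves all genes (a single permuted phenotype vector
#' is one permuted dataset for every gene), preserving the inter-gene
#' correlation of the null. Gene-level empirical p values are then
#' Benjamini-Hochberg adjusted across genes. Genes whose SNPs are absent or
#' monomorphic in the cohort are reported with `status = "no data"`.
#'
#' @param snp_set a [build_snp_set()] result (its provenance drives the
#'   grouping). Gene subsets are ordered by index-eQTL significance before
#'   filtering.
#' @param cohort a [case_control_cohort()].
#' @param n_perms number of phenotype permutations (default 10000).
#' @param seed integer seed.
#' @param max_R independence threshold for the per-gene subsets (default
#'   0.33).
#' @return data.frame with columns `gene_id`, `n_snps`, `sum_chi2`,
#'   `empirical_p`, `bh_adjusted_p`, `status`.
#' @export
gene_level_association <- function(snp_set, cohort, n_perms = 10000L,
                                   seed = 1L, max_R = 0.33) {
  stopifnot(inherits(snp_set, "snp_set"))
  prov <- snp_set$provenance
  genes <- sort(unique(prov$gene_id))
  cohort_ids <- cohort$geno$snps$snp_id
  gene_snps <- lapply(genes, function(g) {
    rows <- prov[prov$gene_id == g, , drop = FALSE]
    rows <- rows[order(rows$index_p, -rows$r2, rows$snp_id), , drop = FALSE]
    cands <- unique(rows$snp_id)
    cands <- cands[cands %in% cohort_ids]
    cands <- cands[vapply(cands, function(s) {
      v <- cohort$geno$dosage[, s]
      v <- v[!is.na(v)]
      length(unique(v)) >= 2
    }, logical(1))]
    if (length(cands) == 0) return(character(0))
    attr(independence_filter(cands, cohort$geno, max_R), "retained")
  })
  names(gene_snps) <- genes
  all_snps <- unique(unlist(gene_snps))
  if (length(all_snps) == 0) {
    return(data.frame(gene_id = genes, n_snps = 0L, sum_chi2 = NA_real_,
                      empirical_p = NA_real_, bh_adjusted_p = NA_real_,
                      status = "no data", stringsAsFactors = FALSE))
  }
  cc <- .cohort_chi2(all_snps, cohort, n_perms, seed)
  out <- data.frame(gene_id = genes, n_snps = 0L, sum_chi2 = NA_real_,
                    empirical_p = NA_real_, bh_adjusted_p = NA_real_,
                    status = "no data", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    snps <- intersect(gene_snps[[i]], cc$members)
    if (length(snps) == 0) next
    idx <- match(snps, cc$members)
    obs <- sum(cc$chi2_obs[idx])
    perm <- colSums(cc$chi2_perm[idx, , drop = FALSE])
    out$n_snps[i] <- length(snps)
    out$sum_chi2[i] <- obs
    out$empirical_p[i] <- as.numeric(empirical_p(obs, perm))
    out$status[i] <- "ok"
  }
  has <- out$status == "ok"
  if (any(has)) out$bh_adjusted_p[has] <- bh_adjust(out$empirical_p[has])
  out
}

#' Classify the direction of a risk allele's effect on expression
#'
#' Re-orients the eQTL slope (expression units per ALT allele) to the risk
#' allele: if the risk allele is REF the sign flips. The classification is
#' invariant under simultaneous allele relabelling and slope sign flip.
#'
#' @param eqtl_beta nonzero eQTL slope per ALT allele.
#' @param risk_allele `"REF"` or `"ALT"`.
#' @return `"risk-increases-expression"` or `"risk-decreases-expression"`.
#' @export
classify_effect_direction <- function(eqtl_beta, risk_allele) {
  if (!risk_allele %in% c("REF", "ALT")) {
    stop("risk_allele must be \"REF\" or \"ALT\"")
  }
  if (is.na(eqtl_beta) || eqtl_beta == 0) stop("no direction: beta is zero")
  b <- if (risk_allele == "ALT") eqtl_beta else -eqtl_beta
  if (b > 0) "risk-increases-expression" else "risk-decreases-expression"
}

#' Catalog enrichment test for the gene set
#'
#' Builds the 2x2 table of genes with versus without catalog disease
#' associations, inside versus outside the set, and applies Fisher's exact
#' test (two-sided).
#'
#' @param set_genes_with_hits,set_genes_total hit count and size of the set.
#' @param background_with_hits,background_total hit count and size of the
#'   background.
#' @return list with `p`, `odds_ratio` and `table`.
#' @export
catalog_enrichment <- function(set_genes_with_hits, set_genes_total,
                               background_with_hits, background_total) {
  if (set_genes_with_hits > set_genes_total ||
      background_with_hits > background_total) {
    stop("hit counts exceed totals")
  }
  if (min(set_genes_with_hits, set_genes_total, background_with_hits,
          background_total) < 0) {
    stop("counts must be non-negative")
  }
  tab <- matrix(c(set_genes_with_hits,
                  set_genes_total - set_genes_with_hits,
                  background_with_hits,
                  background_total - background_with_hits),
                nrow = 2,
                dimnames = list(c("hit", "no_hit"),
                                c("set", "background")))
  ft <- fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}
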