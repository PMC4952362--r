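# Targeted cis-eQTL mapping: score tests for every (gene, cis SNP) pair per
# cell type, sample-label permutation FDR, best-SNP extraction, subgroup
# concordance and exhaustive variable selection at multi-SNP loci.

#' Define the cis window of a gene
#'
#' The gene span extended by `radius_bp` on both sides (strand-ignored),
#' clamped at position 1.
#'
#' @param gene one row of a [gene_annotation()] table (or a list with
#'   `chrom`, `start_bp`, `end_bp`).
#' @param radius_bp window radius (>= 0), default 100 kbp.
#' @return list with `chrom`, `lo_bp`, `hi_bp`.
#' @export
define_cis_window <- function(gene, radius_bp = 100000L) {
  if (radius_bp < 0) stop("radius_bp must be >= 0")
  list(chrom = as.character(gene$chrom),
       lo_bp = max(1L, as.integer(gene$start_bp) - as.integer(radius_bp)),
       hi_bp = as.integer(gene$end_bp) + as.integer(radius_bp))
}

# Residualize the columns of M against the QR of the covariate matrix and
# return the residual matrix plus column norms.
.resid_cols <- function(qx, M) {
  R <- qr.resid(qx, M)
  list(res = R, ss = colSums(R^2))
}

#' Map cis-eQTLs for one cell type with permutation FDR
#'
#' For every gene and every SNP in its cis window (gene span +/- the
#' configured radius) with minor allele frequency at or above the configured
#' floor (computed on the analysed samples after missing-data removal), the
#' GLM score test of expression on genotype adjusted for covariates is
#' computed. The permutation null is built by `n_perms_eqtl` random
#' permutations of genotype sample labels against the fixed
#' (expression, covariate) pairs, which preserves the expression-confounder
#' structure under the null; [permutation_fdr()] is then applied across all
#' (gene, SNP) rows of the cell type and rows are flagged significant at
#' FDR below the configured threshold.
#'
#' @param expr an [expr_matrix()] for one cell type.
#' @param geno a [geno_matrix()].
#' @param covars covariate table with a `sample` column; all other columns
#'   are adjusted for.
#' @param genes a [gene_annotation()] table; genes absent from `expr` are
#'   ignored.
#' @param config a [run_config()] (uses `cis_radius_bp`, `maf_min`,
#'   `n_perms_eqtl`, `eqtl_fdr_threshold`).
#' @param seed integer seed for the permutation stream.
#' @return data.frame (the eQTL table) with columns `gene_id`, `snp_id`,
#'   `cell_type`, `chi2`, `p`, `fdr`, `significant`, `beta_all`; attributes
#'   `skipped_genes` (genes with no testable cis SNP) and `n_samples`.
#' @export
map_cis_eqtls <- function(expr, geno, covars, genes, config, seed) {
  stopifnot(inherits(geno, "geno_matrix"))
  samples <- intersect(rownames(expr), geno_samples(geno))
  samples <- intersect(samples, covars$sample)
  if (length(samples) == 0) stop("no shared samples across inputs")
  if (length(samples) < 20) {
    stop("only ", length(samples),
         " shared samples; at least 20 are required")
  }
  cell_type <- expr_cell_type(expr)
  E_all <- unclass(expr)[samples, , drop = FALSE]
  covars <- covars[match(samples, covars$sample), , drop = FALSE]
  Xc <- as.matrix(covars[, setdiff(names(covars), "sample"), drop = FALSE])
  storage.mode(Xc) <- "double"
  X <- cbind(1, Xc)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix")
  D_all <- geno$dosage[samples, , drop = FALSE]
  maf <- colMeans(D_all, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)

  # enumerate (gene, SNP) pairs within cis windows passing the MAF floor
  meta <- geno$snps
  pair_gene <- character(0); pair_snp <- character(0)
  skipped <- character(0)
  genes_use <- genes[genes$gene_id %in% colnames(E_all), , drop = FALSE]
  for (i in seq_len(nrow(genes_use))) {
    w <- define_cis_window(genes_use[i, ], config$cis_radius_bp)
    hit <- meta$snp_id[meta$chrom == w$chrom & meta$pos >= w$lo_bp &
                         meta$pos <= w$hi_bp]
    hit <- hit[maf[hit] >= config$maf_min & !is.na(maf[hit])]
    hit <- hit[vapply(hit, function(s) {
      v <- D_all[, s]
      length(unique(v[!is.na(v)])) >= 2
    }, logical(1))]
    if (length(hit) == 0) {
      skipped <- c(skipped, genes_use$gene_id[i])
    } else {
      pair_gene <- c(pair_gene, rep(genes_use$gene_id[i], length(hit)))
      pair_snp <- c(pair_snp, hit)
    }
  }
  if (length(pair_gene) == 0) stop("no testable (gene, SNP) pairs")

  n <- length(samples)
  B <- config$n_perms_eqtl
  genes_idx <- unique(pair_gene)
  snps_idx <- unique(pair_snp)
  E <- E_all[, genes_idx, drop = FALSE]
  G <- D_all[, snps_idx, drop = FALSE]
  gi <- match(pair_gene, genes_idx)
  si <- match(pair_snp, snps_idx)
  complete <- !anyNA(E) && !anyNA(G)

  perms <- withr::with_seed(seed, {
    replicate(B, sample.int(n))
  })

  if (complete) {
    qx <- qr(X)
    Er <- .resid_cols(qx, E)
    En <- sweep(Er$res, 2, sqrt(pmax(Er$ss, 1e-300)), "/")
    En_pairs <- En[, gi, drop = FALSE]
    Gr <- .resid_cols(qx, G)
    safe_ss <- pmax(Gr$ss, 1e-300)
    Gn <- sweep(Gr$res, 2, sqrt(safe_ss), "/")
    r_obs <- colSums(En_pairs * Gn[, si, drop = FALSE])
    chi2_obs <- n * r_obs^2
    chi2_obs[Gr$ss[si] <= 1e-12] <- 0
    beta_all <- colSums(Gr$res[, si, drop = FALSE] *
                          Er$res[, gi, drop = FALSE]) / safe_ss[si]
    p_pool <- numeric(B * length(gi))
    for (b in seq_len(B)) {
      Gp <- G[perms[, b], , drop = FALSE]
      Gpr <- .resid_cols(qx, Gp)
      Gpn <- sweep(Gpr$res, 2, sqrt(pmax(Gpr$ss, 1e-300)), "/")
      r <- colSums(En_pairs * Gpn[, si, drop = FALSE])
      chi2 <- n * r^2
      p_pool[(b - 1) * length(gi) + seq_along(gi)] <-
        pchisq(chi2, df = 1, lower.tail = FALSE)
    }
  } else {
    # pairwise-deletion fallback for genotype matrices with missing calls
    chi2_obs <- numeric(length(gi))
    beta_all <- numeric(length(gi))
    for (k in seq_along(gi)) {
      st <- score_test_glm(E[, gi[k]], G[, si[k]], Xc)
      chi2_obs[k] <- st$chi2
      keep <- !is.na(G[, si[k]])
      fit <- lm.fit(cbind(1, Xc, G[, si[k]])[keep, , drop = FALSE],
                    E[keep, gi[k]])
      beta_all[k] <- fit$coefficients[length(fit$coefficients)]
    }
    p_pool <- numeric(B * length(gi))
    for (b in seq_len(B)) {
      Gp <- G[perms[, b], , drop = FALSE]
      for (k in seq_along(gi)) {
        st <- tryCatch(score_test_glm(E[, gi[k]], Gp[, si[k]], Xc),
                       error = function(e) list(chi2 = 0, p = 1))
        p_pool[(b - 1) * length(gi) + k] <- st$p
      }
    }
  }

  p_obs <- pchisq(chi2_obs, df = 1, lower.tail = FALSE)
  fdr <- permutation_fdr(p_obs, p_pool, B,
                         threshold = config$eqtl_fdr_threshold)
  out <- data.frame(gene_id = pair_gene, snp_id = pair_snp,
                    cell_type = cell_type, chi2 = chi2_obs, p = p_obs,
                    fdr = fdr$fdr, significant = fdr$significant,
                    beta_all = beta_all, stringsAsFactors = FALSE)
  attr(out, "skipped_genes") <- skipped
  attr(out, "n_samples") <- n
  out
}

#' Extract the best cis-eQTL SNP per gene and cell type
#'
#' For each (gene, cell type) present in an eQTL table, returns the row with
#' the smallest p value (ties broken by larger chi-squared, then by
#' lexicographically smaller SNP id). The gene x cell-type matrix of
#' `-log10(FDR)` for the selected rows is attached as attribute
#' `fdr_matrix`.
#'
#' @param table an eQTL table from [map_cis_eqtls()] (or several row-bound
#'   cell types).
#' @return data.frame of best rows; attribute `fdr_matrix`.
#' @export
best_snp_per_gene <- function(table) {
  if (nrow(table) == 0) stop("empty eQTL table")
  key <- interaction(table$gene_id, table$cell_type, drop = TRUE)
  ord <- order(key, table$p, -table$chi2, table$snp_id)
  t2 <- table[ord, , drop = FALSE]
  best <- t2[!duplicated(interaction(t2$gene_id, t2$cell_type, drop = TRUE)),
             , drop = FALSE]
  rownames(best) <- NULL
  genes <- sort(unique(best$gene_id))
  cts <- sort(unique(best$cell_type))
  m <- matrix(NA_real_, length(genes), length(cts),
              dimnames = list(genes, cts))
  m[cbind(match(best$gene_id, genes), match(best$cell_type, cts))] <-
    -log10(pmax(best$fdr, 1e-300))
  attr(best, "fdr_matrix") <- m
  best
}

#' Per-subgroup eQTL effect sizes
#'
#' For each significant eQTL row, the OLS slope of expression on dosage
#' (adjusted for the non-grouping covariates) is computed separately within
#' the two levels of a grouping covariate (e.g. disease status), giving the
#' paired slopes used to assess concordance of effects between patients and
#' controls.
#'
#' @param table eQTL table (only rows with `significant == TRUE` are used).
#' @param expr an [expr_matrix()].
#' @param geno a [geno_matrix()].
#' @param covars covariate table including the grouping column.
#' @param group_label name of the 0/1 (or two-level) grouping column,
#'   default `"status"`.
#' @return data.frame with columns `gene_id`, `snp_id`, `cell_type`,
#'   `group1`, `beta1`, `se1`, `group2`, `beta2`, `se2`, `note`.
#' @export
subgroup_concordance <- function(table, expr, geno, covars,
                                 group_label = "status") {
  rows <- table[table$significant, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(data.frame(gene_id = character(), snp_id = character(),
                      cell_type = character(), group1 = character(),
                      beta1 = numeric(), se1 = numeric(),
                      group2 = character(), beta2 = numeric(),
                      se2 = numeric(), note = character()))
  }
  if (!group_label %in% names(covars)) {
    stop("grouping column not in covariates: ", group_label)
  }
  samples <- intersect(rownames(expr), geno_samples(geno))
  samples <- intersect(samples, covars$sample)
  covars <- covars[match(samples, covars$sample), , drop = FALSE]
  lev <- sort(unique(covars[[group_label]]))
  if (length(lev) != 2) stop("grouping column must have exactly two levels")
  split_idx <- lapply(lev, function(l) which(covars[[group_label]] == l))
  if (any(vapply(split_idx, length, integer(1)) < 10)) {
    stop("each subgroup needs at least 10 samples")
  }
  other <- setdiff(names(covars), c("sample", group_label))
  Xo <- as.matrix(covars[, other, drop = FALSE])
  storage.mode(Xo) <- "double"
  E <- unclass(expr)[samples, , drop = FALSE]
  D <- geno$dosage[samples, , drop = FALSE]

  fit_group <- function(idx, gene, snp) {
    y <- E[idx, gene]
    g <- D[idx, snp]
    keep <- !is.na(y) & !is.na(g)
    y <- y[keep]; g <- g[keep]
    if (length(unique(g)) < 2) {
      return(c(beta = NA_real_, se = NA_real_))
    }
    X <- cbind(1, Xo[idx, , drop = FALSE][keep, , drop = FALSE], g)
    fit <- lm(y ~ X - 1)
    k <- ncol(X)
    c(beta = unname(coef(fit)[k]), se = unname(sqrt(diag(vcov(fit)))[k]))
  }
  res <- lapply(seq_len(nrow(rows)), function(r) {
    b1 <- fit_group(split_idx[[1]], rows$gene_id[r], rows$snp_id[r])
    b2 <- fit_group(split_idx[[2]], rows$gene_id[r], rows$snp_id[r])
    note <- if (anyNA(c(b1, b2))) "monomorphic genotype in a subgroup" else ""
    data.frame(gene_id = rows$gene_id[r], snp_id = rows$snp_id[r],
               cell_type = rows$cell_type[r],
               group1 = as.character(lev[1]), beta1 = b1[["beta"]],
               se1 = b1[["se"]], group2 = as.character(lev[2]),
               beta2 = b2[["beta"]], se2 = b2[["se"]], note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Exhaustive variable selection over candidate eQTL SNPs
#'
#' Fits the Gaussian linear model of one gene's expression on every subset
#' of up to 10 candidate SNPs (covariates always retained) and returns the
#' subset minimising the Bayesian information criterion. Ties are broken by
#' smaller subset size, then by the lexicographically smallest sorted id
#' string; the empty subset (covariate-only model) is a valid winner.
#'
#' @param expr_gene numeric vector of one gene's expression.
#' @param candidate_snps dosage matrix (samples x k, k <= 10) with SNP ids
#'   as column names.
#' @param covars optional covariate matrix/data.frame (intercept added).
#' @return list with `selected` (character vector of SNP ids, possibly
#'   empty), `size`, and `bic` of the winning model.
#' @export
exhaustive_selection <- function(expr_gene, candidate_snps, covars = NULL) {
  G <- as.matrix(candidate_snps)
  k <- ncol(G)
  if (k > 10) stop("exhaustive search bound exceeded: k > 10")
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(k))
  y <- as.numeric(expr_gene)
  Xc <- if (is.null(covars)) {
    matrix(1, length(y), 1)
  } else {
    cbind(1, as.matrix(covars))
  }
  storage.mode(Xc) <- "double"
  keep <- !is.na(y) & complete.cases(Xc) & complete.cases(G)
  y <- y[keep]; Xc <- Xc[keep, , drop = FALSE]; G <- G[keep, , drop = FALSE]
  n <- length(y)
  bic_of <- function(X) {
    rss <- sum(qr.resid(qr(X), y)^2)
    n * log(rss / n) + (ncol(X) + 1) * log(n)
  }
  subsets <- lapply(0:(2^k - 1), function(mask) which(bitwAnd(
    mask, 2^(seq_len(k) - 1)) > 0))
  bics <- vapply(subsets, function(ss) {
    bic_of(cbind(Xc, G[, ss, drop = FALSE]))
  }, numeric(1))
  tied <- which(bics <= min(bics) + 1e-8)
  sizes <- vapply(subsets[tied], length, integer(1))
  tied <- tied[sizes == min(sizes)]
  keys <- vapply(subsets[tied], function(ss) {
    paste(sort(colnames(G)[ss]), collapse = ",")
  }, character(1))
  win <- tied[order(keys)][1]
  list(selected = sort(colnames(G)[subsets[[win]]]),
       size = length(subsets[[win]]), bic = bics[win])
}
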