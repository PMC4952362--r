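# Chromatin-mark coverage at eQTL SNPs: counts-per-million at single-base
# SNP positions, enrichment against a random-SNP resampling null from the
# same cis regions, and rank correlation of eQTL strength with acetylation.

# Normalise SNP input to a data.frame with snp_id, chrom, pos.
.snp_positions <- function(snps) {
  if (inherits(snps, "geno_matrix")) snps <- snps$snps
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(snps))) {
    stop("SNP positions need columns chrom and pos")
  }
  if (!"snp_id" %in% names(snps)) {
    snps$snp_id <- paste0(snps$chrom, ":", snps$pos)
  }
  snps
}

#' Coverage counts per million at SNP positions
#'
#' Sums the counts of every track interval overlapping each SNP's single
#' 1-bp position and scales by the track's total mapped reads:
#' `CPM = count * 1e6 / total`.
#'
#' @param track a [coverage_track()] with positive total count.
#' @param snps SNP positions (data.frame with `chrom`, `pos`, optional
#'   `snp_id`, or a [geno_matrix()]).
#' @param window half-width in bp added around each SNP position (default 0:
#'   the single base itself).
#' @return named numeric vector of CPM values, one per SNP.
#' @export
cpm_at_snps <- function(track, snps, window = 0L) {
  if (track$total_count <= 0) stop("track total count is zero")
  snps <- .snp_positions(snps)
  iv <- track$intervals
  counts <- rep(0, nrow(snps))
  if (nrow(iv) > 0) {
    gr_iv <- GenomicRanges::GRanges(iv$chrom,
                                    IRanges::IRanges(iv$start, iv$end))
    gr_snp <- GenomicRanges::GRanges(
      snps$chrom, IRanges::IRanges(pmax(1, snps$pos - window),
                                   snps$pos + window))
    hits <- GenomicRanges::findOverlaps(gr_snp, gr_iv)
    if (length(hits) > 0) {
      agg <- tapply(iv$count[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), sum)
      counts[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  setNames(counts * 1e6 / track$total_count, snps$snp_id)
}

#' Enrichment of coverage at eQTL SNPs against a resampling null
#'
#' The observed statistic is the mean CPM over the eQTL SNPs. The null is
#' built by `n_iter` random draws of the same number of SNPs, sampled
#' without replacement from the candidate pool (all SNPs in the cis regions
#' searched for eQTLs), taking the mean CPM of each draw. The empirical p
#' value is the fraction of null means greater than or equal to the observed
#' mean (one-sided: enrichment above background). When `expanded_snps` is
#' supplied (eQTL SNPs plus their LD proxies), the same comparison is run
#' for the expanded set and returned under `$expanded`.
#'
#' @param eqtl_snps SNP positions of the eQTL SNPs.
#' @param candidate_pool SNP positions of the full cis-region pool (must be
#'   at least as many as the draw size).
#' @param track a [coverage_track()].
#' @param n_iter number of random draws (default 10000).
#' @param seed integer seed.
#' @param expanded_snps optional positions of the LD-expanded SNP list.
#' @param window half-width in bp for the CPM query (default 0).
#' @return list of class `enrichment_result`: `observed_mean_cpm`,
#'   `null_mean`, `null_sd`, `empirical_p`, `n_iter`, `n_snps`, and
#'   optionally `expanded` (same fields for the expanded set).
#' @export
sampling_null_enrichment <- function(eqtl_snps, candidate_pool, track,
                                     n_iter = 10000L, seed = 1L,
                                     expanded_snps = NULL, window = 0L) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  pool <- .snp_positions(candidate_pool)
  pool_cpm <- cpm_at_snps(track, pool, window = window)
  one_run <- function(snps, seed_k) {
    snps <- .snp_positions(snps)
    k <- nrow(snps)
    if (nrow(pool) < k) {
      stop("candidate pool (", nrow(pool),
           ") smaller than the number of SNPs drawn (", k, ")")
    }
    obs <- mean(cpm_at_snps(track, snps, window = window))
    null_means <- withr::with_seed(seed_k, {
      vapply(seq_len(n_iter), function(i) {
        mean(pool_cpm[sample.int(nrow(pool), k)])
      }, numeric(1))
    })
    list(observed_mean_cpm = obs, null_mean = mean(null_means),
         null_sd = sd(null_means),
         empirical_p = mean(null_means >= obs),
         n_iter = as.integer(n_iter), n_snps = k)
  }
  out <- one_run(eqtl_snps, seed)
  if (!is.null(expanded_snps)) out$expanded <- one_run(expanded_snps,
                                                       seed + 1L)
  structure(out, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result:", x$n_snps, "SNPs, observed mean CPM",
      signif(x$observed_mean_cpm, 4), "vs null", signif(x$null_mean, 4),
      "+/-", signif(x$null_sd, 4), "( p =", x$empirical_p, ",", x$n_iter,
      "iterations )\n")
  invisible(x)
}

#' Correlate eQTL strength with acetylation coverage
#'
#' Spearman rank correlation between the chi-squared statistics of the best
#' eQTL SNP per gene (taken regardless of FDR significance) and the
#' coverage CPM at the same SNP positions.
#'
#' @param best_eqtls data.frame with columns `snp_id` and `chi2` (one row
#'   per gene, e.g. from [best_snp_per_gene()] for one cell type).
#' @param track a [coverage_track()].
#' @param snps SNP positions covering the best-eQTL SNP ids.
#' @param window half-width in bp for the CPM query (default 0).
#' @return list with `rho`, `p`, `n` and the per-gene `cpm` vector.
#' @export
strength_vs_acetylation <- function(best_eqtls, track, snps, window = 0L) {
  if (nrow(best_eqtls) < 3) stop("need at least 3 genes")
  snps <- .snp_positions(snps)
  idx <- match(best_eqtls$snp_id, snps$snp_id)
  if (anyNA(idx)) {
    stop("best-eQTL SNP(s) missing from SNP positions: ",
         paste(best_eqtls$snp_id[is.na(idx)], collapse = ", "))
  }
  cpm <- cpm_at_snps(track, snps[idx, , drop = FALSE], window = window)
  res <- tryCatch(
    spearman_rho(best_eqtls$chi2, cpm),
    error = function(e) stop("eQTL strength vs acetylation correlation ",
                             "failed: ", conditionMessage(e), call. = FALSE)
  )
  list(rho = res$rho, p = res$p, n = nrow(best_eqtls), cpm = cpm)
}
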