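# Linkage disequilibrium: composite (dosage-correlation) r-squared, proxy
# tagging at a threshold, and greedy relative-independence filtering on the
# multiple correlation coefficient.

#' Composite LD r-squared between two SNPs
#'
#' Squared Pearson correlation of dosage vectors (composite-LD estimator for
#' unphased data). Samples missing either dosage are dropped pairwise.
#'
#' @param dosages_a,dosages_b dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b)) stop("dosage lengths differ")
  keep <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[keep]; b <- dosages_b[keep]
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) {
    stop("monomorphic input: LD undefined")
  }
  cor(a, b)^2
}

#' Tag SNPs in LD with an index SNP
#'
#' Returns every SNP within `window_bp` of the index on the same chromosome
#' whose dosage r-squared with the index is at least `r2_min` (inclusive
#' threshold). The index SNP always tags itself with r-squared 1.
#'
#' @param index_snp SNP id present in `geno`.
#' @param geno a [geno_matrix()] serving as the LD panel.
#' @param r2_min inclusive r-squared threshold (default 0.8).
#' @param window_bp maximum distance from the index (default 1 Mbp).
#' @return data.frame with columns `index_snp_id`, `proxy_snp_id`, `r2`.
#' @export
tag_snps <- function(index_snp, geno, r2_min = 0.8, window_bp = 1000000L) {
  meta <- geno$snps
  i <- match(index_snp, meta$snp_id)
  if (is.na(i)) stop("index SNP not in genotype matrix: ", index_snp)
  gi <- geno$dosage[, i]
  if (sd(gi, na.rm = TRUE) == 0 || all(is.na(gi))) {
    stop("monomorphic index SNP: ", index_snp)
  }
  cand <- which(meta$chrom == meta$chrom[i] &
                  abs(meta$pos - meta$pos[i]) <= window_bp)
  r2 <- vapply(cand, function(j) {
    gj <- geno$dosage[, j]
    keep <- !is.na(gi) & !is.na(gj)
    if (sum(keep) < 2 || sd(gj[keep]) == 0 || sd(gi[keep]) == 0) {
      return(NA_real_)
    }
    cor(gi[keep], gj[keep])^2
  }, numeric(1))
  hit <- !is.na(r2) & r2 >= r2_min
  out <- data.frame(index_snp_id = index_snp,
                    proxy_snp_id = meta$snp_id[cand[hit]],
                    r2 = r2[hit], stringsAsFactors = FALSE)
  out[order(-out$r2, out$proxy_snp_id), , drop = FALSE]
}

# Multiple correlation of one dosage vector against a set of others:
# sqrt(R^2) from the least-squares regression (with intercept) of `target`
# on the columns of `basis`.
.multiple_corr <- function(target, basis) {
  if (is.null(basis) || NCOL(basis) == 0) return(0)
  X <- cbind(1, as.matrix(basis))
  keep <- !is.na(target) & complete.cases(X)
  y <- target[keep]; X <- X[keep, , drop = FALSE]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  rss <- sum(qr.resid(qr(X), y)^2)
  r2 <- max(0, min(1, 1 - rss / tss))
  sqrt(r2)
}

#' Greedy relative-independence filter on SNP dosages
#'
#' Scans candidates in the supplied order; a candidate is retained iff its
#' multiple correlation coefficient (square root of the R-squared from
#' regressing its dosage on all previously retained dosages, with intercept)
#' does not exceed `max_R`. The first candidate is always retained. The
#' result is deterministic given the ordering.
#'
#' @param snps ordered character vector of candidate SNP ids (the
#'   conventional ordering is descending association significance, ties
#'   broken by id).
#' @param geno a [geno_matrix()] containing the candidates.
#' @param max_R retention threshold on the multiple correlation (default
#'   0.33).
#' @return data.frame with columns `snp_id`, `order`, `multiple_R`,
#'   `retained`; attribute `retained` holds the retained ids in scan order.
#' @export
independence_filter <- function(snps, geno, max_R = 0.33) {
  if (length(snps) == 0) {
    out <- data.frame(snp_id = character(), order = integer(),
                      multiple_R = numeric(), retained = logical())
    attr(out, "retained") <- character(0)
    return(out)
  }
  miss <- setdiff(snps, geno$snps$snp_id)
  if (length(miss) > 0) {
    stop("candidate SNPs absent from genotype matrix: ",
         paste(miss, collapse = ", "))
  }
  D <- geno$dosage[, snps, drop = FALSE]
  mono <- apply(D, 2, function(v) sd(v, na.rm = TRUE) == 0 || all(is.na(v)))
  if (any(mono)) {
    stop("monomorphic candidate SNP(s): ",
         paste(snps[mono], collapse = ", "))
  }
  retained_idx <- integer(0)
  mR <- numeric(length(snps))
  keep <- logical(length(snps))
  for (k in seq_along(snps)) {
    mR[k] <- .multiple_corr(D[, k],
                            if (length(retained_idx) > 0)
                              D[, retained_idx, drop = FALSE] else NULL)
    keep[k] <- mR[k] <= max_R
    if (keep[k]) retained_idx <- c(retained_idx, k)
  }
  out <- data.frame(snp_id = snps, order = seq_along(snps),
                    multiple_R = mR, retained = keep,
                    stringsAsFactors = FALSE)
  attr(out, "retained") <- snps[keep]
  out
}
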