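# Lightweight S3 containers shared across the pipeline stages.

#' Construct a genotype matrix container
#'
#' Holds allele dosages (samples x SNPs, values 0/1/2 or NA) together with
#' per-SNP metadata. Dosage is the count of ALT alleles per sample.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns. Row names
#'   are sample ids, column names SNP ids.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, one row per column of `dosage`, in column order.
#' @param n_skipped integer count of VCF records skipped on load
#'   (multiallelic / non-SNP).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, snps, n_skipped = 0L) {
  dosage <- as.matrix(dosage)
  stopifnot(is.numeric(dosage) || all(is.na(dosage)))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(snps))) {
    stop("snps must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(snps) != ncol(dosage)) {
    stop("snps has ", nrow(snps), " rows but dosage has ", ncol(dosage),
         " columns")
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id in genotype matrix")
  colnames(dosage) <- snps$snp_id
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  }
  ok <- is.na(dosage) | (dosage %in% c(0, 1, 2))
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  structure(
    list(dosage = dosage, snps = snps, n_skipped = as.integer(n_skipped)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "SNPs")
  if (x$n_skipped > 0) cat(" (", x$n_skipped, " records skipped on load)",
                           sep = "")
  cat("\n")
  invisible(x)
}

#' Sample ids of a genotype matrix
#' @param geno a [geno_matrix()].
#' @return character vector of sample ids.
#' @export
geno_samples <- function(geno) rownames(geno$dosage)

#' Subset a genotype matrix
#'
#' @param geno a [geno_matrix()].
#' @param samples optional character vector of sample ids to keep (order
#'   respected). Missing ids are an error.
#' @param snps optional character vector of SNP ids to keep.
#' @return a `geno_matrix`.
#' @export
geno_subset <- function(geno, samples = NULL, snps = NULL) {
  d <- geno$dosage
  meta <- geno$snps
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(d))
    if (length(miss) > 0) {
      stop("samples absent from genotype matrix: ",
           paste(miss, collapse = ", "))
    }
    d <- d[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    miss <- setdiff(snps, colnames(d))
    if (length(miss) > 0) {
      stop("SNPs absent from genotype matrix: ", paste(miss, collapse = ", "))
    }
    d <- d[, snps, drop = FALSE]
    meta <- meta[match(snps, meta$snp_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  geno_matrix(d, meta, geno$n_skipped)
}

#' Minor allele frequencies of a genotype matrix
#'
#' Computed on non-missing calls, folded so values lie in \[0, 0.5\].
#'
#' @param geno a [geno_matrix()].
#' @return named numeric vector, one entry per SNP.
#' @export
geno_maf <- function(geno) {
  f <- colMeans(geno$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Construct an expression matrix container
#'
#' @param values numeric matrix, samples x genes; row names sample ids,
#'   column names gene ids.
#' @param cell_type single label for the cell subset measured.
#' @return matrix of class `expr_matrix` with a `cell_type` attribute.
#' @export
expr_matrix <- function(values, cell_type = "unknown") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs sample row names and gene column names")
  }
  structure(values, cell_type = as.character(cell_type)[1],
            class = c("expr_matrix", class(values)))
}

#' Cell type label of an expression matrix
#' @param expr an [expr_matrix()].
#' @return character scalar.
#' @export
expr_cell_type <- function(expr) attr(expr, "cell_type")

#' Construct a coverage track
#'
#' Intervals are stored 1-based inclusive (converted from BED half-open on
#' read). Overlapping intervals are allowed; counts sum on query.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and `count` (non-negative).
#' @param total_count total mapped reads used for CPM scaling; defaults to
#'   the sum of interval counts.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(intervals = data.frame(chrom = character(),
                                                  start = integer(),
                                                  end = integer(),
                                                  count = numeric()),
                           total_count = sum(intervals$count)) {
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "count")
  if (!all(req %in% names(intervals))) {
    stop("intervals must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(intervals) > 0) {
    if (any(intervals$end < intervals$start)) stop("interval end < start")
    if (any(intervals$count < 0)) stop("negative interval count")
  }
  if (length(total_count) == 0 || is.na(total_count)) total_count <- 0
  structure(list(intervals = intervals, total_count = as.numeric(total_count)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", nrow(x$intervals), "intervals, total count",
      x$total_count, "\n")
  invisible(x)
}

#' Construct a case-control cohort
#'
#' @param geno a [geno_matrix()] for the cohort samples.
#' @param phenotype data.frame with columns `sample` and `case` (0/1),
#'   covering exactly the genotype samples.
#' @return an object of class `case_control_cohort`.
#' @export
case_control_cohort <- function(geno, phenotype) {
  stopifnot(inherits(geno, "geno_matrix"))
  phenotype <- as.data.frame(phenotype, stringsAsFactors = FALSE)
  if (!all(c("sample", "case") %in% names(phenotype))) {
    stop("phenotype must have columns sample, case")
  }
  if (!all(phenotype$case %in% c(0, 1))) stop("case must be 0/1")
  if (!setequal(phenotype$sample, geno_samples(geno))) {
    stop("phenotype samples do not match genotype samples")
  }
  phenotype <- phenotype[match(geno_samples(geno), phenotype$sample), ]
  rownames(phenotype) <- NULL
  structure(list(geno = geno, phenotype = phenotype),
            class = "case_control_cohort")
}

#' @export
print.case_control_cohort <- function(x, ...) {
  cat("case_control_cohort:", sum(x$phenotype$case == 1), "cases,",
      sum(x$phenotype$case == 0), "controls,", ncol(x$geno$dosage), "SNPs\n")
  invisible(x)
}

#' Gene annotation table constructor
#'
#' @param gene_id character vector of unique gene ids.
#' @param chrom chromosome per gene.
#' @param start_bp,end_bp 1-based inclusive gene span.
#' @return data.frame with class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start_bp, end_bp) {
  if (anyDuplicated(gene_id)) stop("gene_id must be unique")
  if (any(end_bp < start_bp)) stop("gene end_bp < start_bp")
  structure(
    data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
               start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
               stringsAsFactors = FALSE),
    class = c("gene_annotation", "data.frame")
  )
}
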