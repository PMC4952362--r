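# VCF genotype I/O. Parsing goes through vcfR; writing emits minimal
# plain-text VCFv4.2 with GT-only genotype fields so files round-trip through
# the reader.

#' Load biallelic SNP dosages from a VCF file
#'
#' Reads GT fields and converts each call to an ALT-allele dosage in
#' \{0, 1, 2\} (missing calls become `NA`). Multiallelic records and records
#' whose REF or ALT is not a single base are skipped and counted. Rows are
#' sorted by (chrom, pos). Records without an ID get `chrom:pos` as SNP id.
#'
#' @param path VCF file (plain text or gzipped).
#' @param sample_subset optional character vector of sample ids to keep;
#'   ids absent from the file are an error.
#' @return a [geno_matrix()]; `n_skipped` records the skipped record count,
#'   and attribute `genome_build` carries any `##reference`/`##contig
#'   assembly` string found in the header (else `NA`).
#' @export
load_genotypes_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  base <- c("A", "C", "G", "T")
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    toupper(fix$REF) %in% base & toupper(fix$ALT) %in% base
  keep[is.na(keep)] <- FALSE
  n_skipped <- sum(!keep)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT genotype fields: ", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic SNP records in ", path)

  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, samples)
    if (length(miss) > 0) {
      stop("requested sample(s) absent from VCF: ",
           paste(miss, collapse = ", "))
    }
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }

  dos <- .gt_to_dosage(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = toupper(fix$REF),
                     alt = toupper(fix$ALT), stringsAsFactors = FALSE)
  ord <- order(snps$chrom, snps$pos, snps$snp_id)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  dos <- t(dos[ord, , drop = FALSE])
  rownames(dos) <- samples

  build <- NA_character_
  meta <- vcf@meta
  ref_line <- grep("^##reference=", meta, value = TRUE)
  if (length(ref_line) > 0) build <- sub("^##reference=", "", ref_line[1])
  out <- geno_matrix(dos, snps, n_skipped)
  attr(out, "genome_build") <- build
  out
}

# GT string matrix (SNPs x samples) -> numeric dosage matrix.
.gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == "." | alleles == "")) return(NA_real_)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a) || any(a > 1)) return(NA_real_)
    sum(a)
  }, numeric(1))
  out <- matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  out
}

#' Write a genotype matrix as plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with GT-only genotype columns (dosage 0 ->
#' `0/0`, 1 -> `0/1`, 2 -> `1/1`, `NA` -> `./.`), suitable for re-reading
#' with [load_genotypes_vcf()].
#'
#' @param geno a [geno_matrix()].
#' @param path output file path.
#' @param genome_build optional build string written as `##reference=`.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path, genome_build = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  snps <- geno$snps
  d <- geno$dosage
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  idx <- !is.na(t(d))
  gt[idx] <- gt_code[t(d)[idx] + 1]
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(genome_build)) paste0("##reference=", genome_build),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  )
  body <- paste(snps$chrom, snps$pos, snps$snp_id, snps$ref, snps$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
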