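# Tabular I/O: expression matrices, covariates, phenotypes, gene annotations
# and coverage tracks.

#' Load a normalized expression matrix from TSV
#'
#' Expected layout: one row per gene, first column gene id, remaining columns
#' one per sample with sample ids in the header row.
#'
#' @param path TSV file.
#' @param cell_type label attached to the returned matrix.
#' @return an [expr_matrix()] (samples x genes).
#' @export
load_expression_tsv <- function(path, cell_type = "unknown") {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- genes
  expr_matrix(m, cell_type)
}

#' Write an expression matrix to TSV (genes x samples layout)
#' @param expr an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  tab <- data.frame(gene_id = colnames(expr), t(unclass(expr)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a per-sample covariate table from TSV
#'
#' Columns: `sample`, `status` (0/1 disease status), plus any further
#' covariates (e.g. `sex`, `age`, `batch`).
#'
#' @param path TSV file.
#' @return data.frame with a `sample` column first.
#' @export
load_covariates_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!"sample" %in% names(tab)) stop("covariate table needs a sample column")
  tab$sample <- as.character(tab$sample)
  tab
}

#' Write a covariate table to TSV
#' @param covars data.frame with a `sample` column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_covariates_tsv <- function(covars, path) {
  write.table(covars, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a case-control phenotype table from TSV
#'
#' Columns: `sample`, `case` (0/1).
#'
#' @param path TSV file.
#' @return data.frame with columns `sample`, `case`.
#' @export
load_phenotype_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("sample", "case") %in% names(tab))) {
    stop("phenotype table needs columns sample, case")
  }
  if (!all(tab$case %in% c(0, 1))) stop("case must be 0/1 in ", path)
  tab$sample <- as.character(tab$sample)
  tab
}

#' Write a phenotype table to TSV
#' @param phen data.frame with columns `sample`, `case`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(phen, path) {
  write.table(phen[, c("sample", "case")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Load gene annotations from GFF3 or 4-column BED
#'
#' GFF3 files are parsed with `rtracklayer::import` and filtered to `gene`
#' features (falling back to all features if none are typed `gene`); the gene
#' id is taken from the `ID`, `gene_id` or `Name` attribute, in that order.
#' BED input (detected by a `.bed` extension) must have 4 columns
#' chrom/start/end/name with 0-based half-open coordinates.
#'
#' @param path annotation file.
#' @return a [gene_annotation()] table (1-based inclusive spans).
#' @export
load_gene_annotations <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop("gene BED needs 4 columns: chrom start end name")
    return(gene_annotation(tab[[4]], tab[[1]], tab[[2]] + 1L, tab[[3]]))
  }
  gr <- rtracklayer::import(path)
  types <- as.character(gr$type)
  if (!is.null(types) && any(types == "gene")) gr <- gr[types == "gene"]
  md <- S4Vectors::mcols(gr)
  ids <- NULL
  for (field in c("ID", "gene_id", "Name")) {
    if (field %in% names(md) && !all(is.na(md[[field]]))) {
      ids <- as.character(md[[field]])
      break
    }
  }
  if (is.null(ids)) stop("no gene id attribute (ID/gene_id/Name) in ", path)
  gene_annotation(ids, as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Write gene annotations as GFF3
#' @param genes a [gene_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$chrom, "cytoqtl", "gene", genes$start_bp,
                   genes$end_bp, ".", "+", ".",
                   paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Load a coverage track from BED/bedGraph
#'
#' Expects 4 whitespace-separated columns: chrom, start, end, count, with
#' 0-based half-open BED coordinates. Intervals are converted to the internal
#' 1-based inclusive convention; the summed count is recorded as the track
#' total for CPM scaling.
#'
#' @param path BED/bedGraph file.
#' @return a [coverage_track()].
#' @export
load_coverage_bed <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (file.size(path) == 0) return(coverage_track())
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  tab <- tab[!grepl("^(track|browser)", tab[[1]]), , drop = FALSE]
  if (nrow(tab) == 0) return(coverage_track())
  if (ncol(tab) < 4) stop("coverage BED needs 4 columns: chrom start end count")
  start0 <- as.numeric(tab[[2]])
  end0 <- as.numeric(tab[[3]])
  count <- as.numeric(tab[[4]])
  bad <- which(end0 <= start0)
  if (length(bad) > 0) {
    stop("interval end <= start at line ", bad[1], " of ", path)
  }
  bad <- which(count < 0)
  if (length(bad) > 0) {
    stop("negative count at line ", bad[1], " of ", path)
  }
  coverage_track(data.frame(chrom = as.character(tab[[1]]),
                            start = as.integer(start0 + 1),
                            end = as.integer(end0),
                            count = count, stringsAsFactors = FALSE))
}

#' Write a coverage track as BED (0-based half-open) with a count column
#' @param track a [coverage_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coverage_bed <- function(track, path) {
  iv <- track$intervals
  if (nrow(iv) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(paste(iv$chrom, iv$start - 1L, iv$end, iv$count, sep = "\t"),
             path)
  invisible(path)
}

#' Write a generic result table as TSV with fixed column order
#' @param tab data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
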