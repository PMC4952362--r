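# Run configuration: the analysis constants, file paths and the scenario for
# the synthetic stage, serialised as versioned YAML.

.config_schema_version <- 1L

.default_config <- function() {
  list(
    schema_version = .config_schema_version,
    seed = 1L,
    cis_radius_bp = 100000L,
    maf_min = 0.05,
    eqtl_fdr_threshold = 0.10,
    n_perms_eqtl = 320L,
    n_perms_set = 10000L,
    n_iter_null = 10000L,
    r2_tag_min = 0.8,
    max_multiple_corr = 0.33,
    tag_window_bp = 1000000L,
    mhc_region = list(chrom = "chr6", start_bp = 25000000L,
                      end_bp = 34000000L),
    stages = c("simulate", "eqtl", "select", "setassoc", "chromatin"),
    out_dir = "cytoqtl_out",
    paths = list(
      genotypes_vcf = NULL, expression_tsv = NULL, covariates_tsv = NULL,
      genes_gff = NULL, cohort_vcf = NULL, phenotype_tsv = NULL,
      coverage_bed = NULL
    ),
    scenario = NULL
  )
}

#' Create a validated run configuration
#'
#' Collects the analysis constants (cis-window radius, MAF floor, FDR
#' threshold, permutation counts, LD tagging and independence thresholds, the
#' MHC exclusion region), the input/output paths and, optionally, a synthetic
#' scenario for the simulate stage.
#'
#' @param ... named overrides of the defaults; unknown names are an error.
#'   Fields: `seed`, `cis_radius_bp` (default 100000), `maf_min` (0.05),
#'   `eqtl_fdr_threshold` (0.10), `n_perms_eqtl` (320), `n_perms_set` (10000),
#'   `n_iter_null` (10000), `r2_tag_min` (0.8), `max_multiple_corr` (0.33),
#'   `tag_window_bp`, `mhc_region` (list: chrom, start_bp, end_bp), `stages`,
#'   `out_dir`, `paths` (named list), `scenario` (see [sim_scenario()]).
#'
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  cfg <- .default_config()
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all run_config arguments must be named")
    }
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
    }
    for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  }
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg a list with run_config fields.
#' @return the validated config, classed `run_config`.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(.default_config()))
  if (length(unknown) > 0) {
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
  }
  fracs <- c("maf_min", "eqtl_fdr_threshold", "r2_tag_min",
             "max_multiple_corr")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop(f, " must be a single fraction in [0, 1]")
    }
  }
  counts <- c("n_perms_eqtl", "n_perms_set", "n_iter_null")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop(f, " must be an integer >= 1")
    }
    cfg[[f]] <- as.integer(v)
  }
  if (!is.numeric(cfg$cis_radius_bp) || cfg$cis_radius_bp < 0) {
    stop("cis_radius_bp must be >= 0")
  }
  cfg$cis_radius_bp <- as.integer(cfg$cis_radius_bp)
  cfg$tag_window_bp <- as.integer(cfg$tag_window_bp)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stop("seed must be a single integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  m <- cfg$mhc_region
  if (!is.list(m) || !all(c("chrom", "start_bp", "end_bp") %in% names(m))) {
    stop("mhc_region must be a list with chrom, start_bp, end_bp")
  }
  if (m$end_bp < m$start_bp) stop("mhc_region end_bp < start_bp")
  bad_stage <- setdiff(cfg$stages,
                       c("simulate", "eqtl", "select", "setassoc",
                         "chromatin"))
  if (length(bad_stage) > 0) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  }
  if (!is.null(cfg$scenario) && !inherits(cfg$scenario, "sim_scenario")) {
    cfg$scenario <- do.call(sim_scenario, cfg$scenario)
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param cfg a [run_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  if (!is.null(out$scenario)) {
    out$scenario <- unclass(out$scenario)
    # yaml drops names of atomic vectors; maps survive the round trip
    out$scenario$covariate_effects <-
      as.list(out$scenario$covariate_effects)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file written by [write_run_config()] (or hand-edited with
#'   the same schema).
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sv <- cfg$schema_version
  if (is.null(sv) || sv != .config_schema_version) {
    stop("unsupported config schema_version: ",
         if (is.null(sv)) "<missing>" else sv)
  }
  if (!is.null(cfg$stages)) cfg$stages <- as.character(unlist(cfg$stages))
  validate_config(cfg)
}
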