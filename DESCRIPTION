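Package: cytoqtl
Title: Targeted cis-eQTL Mapping and Gene-Set Disease Association for a
    Cytokine Gene Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for targeted analysis of regulatory
    variation in a gene network across leucocyte subsets: cis-eQTL mapping
    with a generalised-linear-model score test and sample-label permutation
    FDR, linkage-disequilibrium tagging (r^2 >= 0.8) and relative-independence
    filtering (multiple correlation <= 0.33) to build an eQTL SNP set,
    self-contained permutation-based SNP-set and gene-level case-control
    association testing with genomic-control inflation statistics (lambda and
    lambda_1000), and chromatin-mark (H3K27ac-style) coverage enrichment at
    eQTL SNPs against a resampling null. Includes a synthetic-cohort
    generator (genotypes with LD block structure, expression with planted
    additive effects, logistic disease phenotypes, coverage tracks with
    peaks) so every stage is testable without access to managed cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    vcfR,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
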