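# cytoqtl

Targeted analysis of regulatory genetic variation in a candidate gene
network. `cytoqtl` is built for the situation where a biologically defined
set of genes — the motivating case is the TNF-superfamily cytokine
signalling network profiled across sorted leucocyte subsets — is to be
interrogated end to end: map cis-eQTLs per cell type, turn the eQTL SNPs
into a marker set for the network, test that set (and each gene) for
case-control disease association, and ask whether the eQTL SNPs sit in
active-enhancer chromatin. It is aimed at statistical geneticists and
computational immunologists who want the whole chain reproducible from a
single seeded configuration, and testable on synthetic cohorts when the
real genotype data are managed-access.

## The statistics at the core

**cis-eQTL score test.** For expression *y*, covariates *X* and dosage *d*,
the addition of genotype to the Gaussian GLM *y = Xβ + γd + ε* is tested
with Rao's score statistic at the null fit,

> T = (d̃ᵀỹ)² / (σ̂₀² · d̃ᵀd̃) = n · corr²(ỹ, d̃) ~ χ²₁,

where tildes denote residuals on *X*. SNPs within the gene span ± 100 kbp
with MAF ≥ 5 % are tested; the FDR is estimated by permuting genotype
sample labels (320 permutations), pooling the permuted p values, and
applying the plug-in estimator with monotonization; calls use FDR < 0.10.

**eQTL SNP set.** Each gene's best significant eQTL SNP is expanded to LD
proxies (dosage r² ≥ 0.8), intersected with the cohort chip, stripped of
MHC-overlapping genes, and filtered for relative independence (multiple
correlation coefficient ≤ 0.33, greedy in significance order).

**Self-contained association.** Per-SNP allelic χ² (1 df, 2×2 allele
counts) summed over the set; phenotypes permuted 10,000 times; empirical
p = fraction of permuted sums greater than observed. Inflation is
summarised by λ = median(χ²)/0.455 and its rescaling

> λ₁₀₀₀ = 1 + (λ − 1) · (1/n_cases + 1/n_controls) / (1/1000 + 1/1000).

The same machinery gives per-gene empirical p values (one shared
permutation stream), BH-adjusted across genes.

**Chromatin enrichment.** Coverage counts per million at each eQTL SNP's
position, compared with 10,000 random draws of equally many SNPs from the
same cis regions (sampling without replacement; one-sided p), plus the
Spearman correlation of eQTL χ² with acetylation.

## Worked example

The shipped scenario simulates 12 genes with 5 cis SNPs each (LD blocks,
ρ = 0.8), 200 expression samples in two cell types with six planted eQTLs,
a 600/600 case-control cohort in which two of the eQTL SNPs carry odds
ratios of 1.4, and a coverage track with peaks at three eQTL SNPs.

```r
library(cytoqtl)

cfg <- run_config(seed = 7, scenario = demo_scenario(),
                  out_dir = file.path(tempdir(), "demo"))
report <- run_pipeline(cfg)

eqtl <- read.table(file.path(cfg$out_dir, "eqtl_CD4.tsv"),
                   header = TRUE, sep = "\t")
head(eqtl[order(eqtl$p), c("gene_id", "snp_id", "chi2", "p", "fdr")], 3)
#>   gene_id   snp_id     chi2            p fdr
#> 3    G001 G001_S03 84.69278 3.485210e-20   0
#> 2    G001 G001_S02 72.19539 1.949101e-17   0
#> 4    G001 G001_S04 65.62380 5.457564e-16   0
```

The planted CD4 eQTL in gene G001 (β = 1.2 at `G001_S03`) is recovered with
its LD-block neighbours; the score χ² of 84.7 on 200 samples corresponds to
a partial correlation of about 0.65.

```r
set_res <- read.table(file.path(cfg$out_dir, "set_assoc.tsv"),
                      header = TRUE, sep = "\t")
set_res[, c("lambda_genome", "lambda_set", "lambda_1000_set",
            "empirical_p", "n_snps")]
#>   lambda_genome lambda_set lambda_1000_set empirical_p n_snps
#> 1      1.820151   4.304622        6.507703           0      7
```

The 7-SNP eQTL set is strongly inflated relative to the genome-wide
independence-filtered SNPs of the same cohort, and none of the 10,000
permuted sums exceeds the observed sum (reported as `<1e-04` in the
`p_report` column). λ₁₀₀₀ upscales λ because this cohort (600/600) is
smaller than the 1000/1000 reference.

```r
genes <- read.table(file.path(cfg$out_dir, "gene_assoc.tsv"),
                    header = TRUE, sep = "\t")
head(genes[order(genes$bh_adjusted_p), ], 4)
#>   gene_id n_snps  sum_chi2 empirical_p bh_adjusted_p status
#> 4    G004      1 20.654097      0.0000      0.000000     ok
#> 1    G001      1  9.433344      0.0014      0.004900     ok
#> 3    G003      1  4.703024      0.0228      0.053200     ok
#> 5    G005      1  1.958329      0.1437      0.251475     ok
```

Gene-level testing attributes the association to G004 and G001 — exactly
the two genes whose eQTL SNPs carry the planted odds ratios.

```r
enr <- read.table(file.path(cfg$out_dir, "enrichment.tsv"),
                  header = TRUE, sep = "\t")
enr[, c("set", "observed_mean_cpm", "null_mean", "null_sd", "empirical_p")]
#>           set observed_mean_cpm null_mean  null_sd empirical_p
#> 1   eqtl_snps          14200.71  1737.084 2623.126      0.0006
#> 2 ld_expanded          14200.71  1637.988 2592.570      0.0012
```

Coverage peaks were planted at the eQTL SNPs, so their mean CPM exceeds the
resampling null by far (one-sided p = 6×10⁻⁴ over 10,000 draws).

A command-line wrapper over the same stages ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cytoqtl.R",package="cytoqtl"))')" \
    all --config cfg.yaml --seed 7 --out outdir
```

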