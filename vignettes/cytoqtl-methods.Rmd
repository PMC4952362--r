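---
title: "Methods: targeted eQTL mapping and gene-set disease association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted eQTL mapping and gene-set disease association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoqtl)
```

# Overview

`cytoqtl` implements a targeted analysis of regulatory variation in a
candidate gene network (the motivating case is the TNF-superfamily cytokine
signalling network across sorted leucocyte subsets). The pipeline has four
analytic stages, each usable on its own:

1. **cis-eQTL mapping** per cell type with a Gaussian GLM score test and a
   sample-label permutation FDR;
2. **eQTL SNP-set construction**: LD tagging of each gene's best eQTL SNP,
   intersection with a case-control cohort's chip, exclusion of MHC genes,
   and relative-independence filtering;
3. **self-contained disease association** of the set and of each gene by a
   phenotype-permutation sum-of-χ² test, with genomic-control inflation
   statistics λ and λ₁₀₀₀;
4. **chromatin-mark enrichment**: coverage (counts per million) at eQTL SNPs
   compared with a resampling null drawn from the same cis regions.

A synthetic-cohort generator provides genotype, expression, phenotype and
coverage data with the statistical structure the analysis assumes, so the
whole pipeline is exercised and calibrated without access to managed cohort
data.

# The eQTL model and score test

For gene $g$ and SNP $s$ in one cell type, expression $y$ is modelled as a
Gaussian GLM on covariates $X$ (disease status, sex, age, batch — whatever
columns the covariate table carries) with genotype dosage $d \in \{0,1,2\}$
as the candidate addition:

$$ y = X\beta + \gamma d + \varepsilon, \qquad \varepsilon \sim N(0,
\sigma^2). $$

The test of $\gamma = 0$ is Rao's score test evaluated at the null
(covariate-only) fit with the null maximum-likelihood variance estimate.
Writing $\tilde y$ and $\tilde d$ for the residuals of expression and dosage
on $X$ (with intercept), the statistic is

$$ T = \frac{(\tilde d^\top \tilde y)^2}{\hat\sigma_0^2\, \tilde d^\top
\tilde d} = n \cdot \mathrm{corr}^2(\tilde y, \tilde d), $$

i.e. $n$ times the squared partial correlation — an identity the test suite
verifies against an explicit double-regression oracle on hundreds of random
instances. $T$ is compared with $\chi^2_1$ in the upper tail (the one-tailed
reading of a chi-squared score). The statistic is invariant to affine
rescaling of expression, so normalisation scale does not matter.

**Cis window.** SNPs within the gene span ± 100 kbp (configurable
`cis_radius_bp`) are tested, strand-ignored and clamped at position 1. SNPs
must have minor allele frequency ≥ `maf_min` (default 0.05) computed on the
analysed, non-missing samples of that cell type.

**Permutation FDR.** The null family is built by permuting *genotype* sample
labels against the fixed (expression, covariate) pairs — this side of the
permutation preserves the expression–confounder structure under the null,
which permuting expression would destroy. One permutation of the sample
labels serves the entire (gene, SNP) family, and `n_perms_eqtl` (default
320) permutations form a pooled null. For an observed p value $t$,

$$ \widehat{\mathrm{FDR}}(t) = \min\!\left(1, \frac{\#\{p^{perm} \le t\} /
B}{\max(\#\{p^{obs} \le t\}, 1)}\right), $$

monotonized so the estimate is non-decreasing in $t$ (each value becomes the
minimum estimate at or above its threshold). Rows with FDR < 0.10 (default
`eqtl_fdr_threshold`) are significant. The estimator is computed over all
(gene, SNP) pairs within a cell type; an alternative — per-gene best
statistics — would change the resolution of the null but not the machinery,
and is not implemented.

**Downstream extractions.** `best_snp_per_gene()` takes the smallest p per
(gene, cell type), breaking ties by larger χ² then lexicographic SNP id.
`subgroup_concordance()` refits the slope by OLS separately in the two
levels of a grouping covariate (patients vs controls) with the remaining
covariates retained. `exhaustive_selection()` enumerates all $2^k$ subsets
($k \le 10$) of a gene's significant SNPs and minimises BIC with covariates
always retained; ties prefer smaller subsets, then the lexicographically
smallest id set. BIC was chosen over AIC or adjusted $R^2$ because it is
consistent for subset selection at fixed $k$ and deterministic; the
criterion is a documented default, not a claim about the original choice.

# LD tagging and relative independence

LD between SNPs is the squared Pearson correlation of dosage vectors
(composite LD — appropriate for unphased data and exactly testable).
`tag_snps()` returns all SNPs within 1 Mbp of an index SNP with
$r^2 \ge$ `r2_tag_min` (default 0.8, inclusive).

`independence_filter()` performs a greedy scan in a supplied order (by
convention descending index-eQTL significance): a candidate is retained iff
its multiple correlation coefficient — the square root of $R^2$ from
regressing its dosage on all previously retained dosages, with intercept —
is at most `max_multiple_corr` (default 0.33). The first candidate is always
retained, and the trace (every candidate's multiple R and decision) is
returned for auditing.

Two audit notions deserve care. The filter's exact guarantee is
*sequential*: each retained SNP satisfied the bound against its
predecessors, each removed SNP violated it; the test suite re-derives both
with an independent `lm()` oracle on every run. A *joint* audit (each
retained SNP against all other retained SNPs) is only meaningful when the
retained count $k$ is well below the sample size $n$: the OLS multiple
correlation of one SNP on $k-1$ others is mechanically of order
$\sqrt{k/n}$ even for mutually independent SNPs, so at $k \sim 100$,
$n \sim 400$ a joint audit fails on pure noise. The suite therefore runs the
joint audit on sets with $k \ll n$, where it passes.

# SNP-set and gene-level disease association

`build_snp_set()` assembles the analysis set: every significant best-eQTL
SNP is expanded to its $r^2 \ge 0.8$ proxies in an LD panel, proxies are
intersected with the SNPs present in the case-control cohort, SNPs whose
source gene overlaps the MHC region are removed, and the remainder is
independence-filtered in the cohort's own genotypes, scanning in index-eQTL
significance order. A SNP tagging several genes enters the set once but
keeps all provenance rows. The MHC rule is a coordinate interval (default
chr6:25,000,000–34,000,000, configurable with the genome build of the
inputs) because long-range MHC LD can lend any nearby eQTL a spurious
disease association.

`set_association()` computes per-SNP allelic χ² statistics — Pearson's test
on the 2×2 allele-count table, 1 df, no continuity correction (a Yates flag
exists for sensitivity only) — sums them over the set, and permutes
case-control labels `n_perms_set` (default 10,000) times, leaving genotypes
untouched so inter-SNP LD is preserved under the null. The empirical p is
the fraction of permuted sums *strictly greater* than the observed sum;
ties count as not greater, so the value can be exactly 0, in which case the
printed form is `<1/n_perms`; the conservative $(b+1)/(B+1)$ variant is
reported alongside. Allele-count margins depend only on genotypes and are
permutation-invariant, so monomorphic SNPs are detected once and dropped
with a log rather than aborting.

Inflation is summarised by the median-based genomic-control factor
$\lambda = \mathrm{median}(\chi^2) / 0.4549364231$ and rescaled to a
1000-case/1000-control cohort:

$$ \lambda_{1000} = 1 + (\lambda - 1)\cdot
\frac{1/n_{cases} + 1/n_{controls}}{1/1000 + 1/1000}. $$

λ is affine in the median, has fixed point 1, and equals the raw λ at
1000/1000 — identities asserted in the tests. On small SNP sets λ is a
noisy summary (the median of a handful of χ² values); it is reported for
comparability, with the permutation p value carrying the inference.

`gene_level_association()` groups the set by source gene, independently
re-filters each gene's proxies at ≤ 0.33, and applies the same sum-of-χ²
test per gene. One permutation stream is shared across genes — a single
permuted phenotype vector is one permuted dataset for every gene — which
preserves the inter-gene correlation of the null and halves the
computation. Gene-level empirical p values are Benjamini–Hochberg adjusted
across genes; genes with no surviving SNPs are reported as `"no data"`
rather than silently dropped. On null fixtures the suite checks that gene
length does not correlate with the gene-level p.

`classify_effect_direction()` re-orients the eQTL slope (per ALT allele) to
the risk allele so that "risk increases/decreases expression" is invariant
under allele relabelling. `catalog_enrichment()` is a two-sided Fisher exact
test on the set-vs-background hit table.

# Chromatin coverage enrichment

Coverage tracks are interval lists with counts (BED/bedGraph input,
converted to 1-based inclusive internally; overlapping intervals sum).
`cpm_at_snps()` evaluates coverage at the single base of each SNP —
"intersecting a SNP" is read minimally as overlap of its 1-bp position,
with a `window` argument for wider readings — scaled to counts per million
by the track total.

`sampling_null_enrichment()` compares the mean CPM over the eQTL SNPs with
`n_iter` (default 10,000) draws of the same number of SNPs sampled *without
replacement* from the cis-region pool (mirroring a finite-pool selection).
The p value is one-sided (fraction of null means ≥ observed), since the
question is enrichment above background. An LD-expanded variant replaces
the eQTL SNPs with the eQTL SNPs plus all their $r^2 \ge 0.8$ proxies.
`strength_vs_acetylation()` is the Spearman rank correlation (average ranks
for ties, large-sample p) between best-eQTL χ² — taken regardless of
significance — and CPM at the same SNPs.

# The synthetic cohorts

The generator emulates exactly the structure the analysis assumes, no more:

* **Genotypes** — biallelic SNPs in LD blocks. Within a block, haplotypes
  follow a copying model: the first allele is Bernoulli($p$), each
  subsequent allele copies its left neighbour with probability `ld_rho`
  (default 0.8), else is redrawn. All SNPs of a block share one allele
  frequency drawn uniformly from `maf_range` (default 0.05–0.45), so
  marginal MAF respects the range exactly. Crucially, block frequencies are
  fixed by the scenario (`freq_seed`), i.e. they are *population*
  parameters: every cohort drawn from one scenario shares them. Without
  this, pooled case-control sampling would mix pools with different
  frequencies asymmetrically and manufacture stratification-like inflation.
  A haplotype-copying model was preferred over coalescent simulation
  because the analysis only needs controllable LD magnitudes.
* **Expression** — intercept 8 (a typical log2 microarray intensity) plus
  linear covariate effects, plus `beta` expression units per ALT allele for
  each planted (gene, SNP, cell type) triple, plus Gaussian noise
  (`noise_sd`, default 1 — matching the GLM the score test assumes).
* **Disease** — a logistic model on the planted SNPs'
  log odds ratios, with the intercept tuned by bisection so the expected
  case fraction matches the target, and sampling over regenerated genotype
  pools until exactly `n_cases` and `n_controls` (default 1000/1000) are
  collected, so λ₁₀₀₀ has fixed denominators.
* **Coverage** — `library_size` reads (default 100,000) of length 100 bp:
  uniform background plus, when peaks are defined, half the library placed
  Normal(peak SNP, 200 bp). The emitted interval counts sum to the library
  size exactly.

What the generator does **not** emulate: microarray probe effects and
saturation, population structure and relatedness, imputation uncertainty,
genotyping error, and spatially realistic ChIP-seq fragment distributions.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under its own assumptions — not that those assumptions hold
in any particular real cohort.

# Numerical and design choices

* Internal coordinates are 1-based inclusive (VCF convention); BED is
  converted on read and write. Multiallelic and non-SNP VCF records are
  skipped and counted, not split.
* One global seed; each pipeline stage derives its own stream by a fixed
  offset, so re-running a config is byte-identical, and stages are
  insensitive to each other's draw counts.
* Degenerate inputs fail loudly: monomorphic genotypes, rank-deficient
  covariates, zero-margin 2×2 tables, constant vectors in correlations and
  empty statistic vectors are errors, except where the analysis
  specifically expects attrition (zero-margin SNPs in a cohort are dropped
  with a log; genes with no testable cis SNPs go to a skip list).
* Ties: best-SNP extraction prefers larger χ² then smaller id; exhaustive
  selection prefers smaller subsets then lexicographic ids; empirical p
  counts ties as not greater (with the conservative variant alongside).
* The score statistic guards against a genotype lying in the covariate
  span (statistic 0, not an error), distinguishing it from a monomorphic
  genotype (an error).
* The `empirical_p` granularity is $1/B$; results quoted as 0 are printed
  `<1/B`.

# Problem sizes

The shipped demonstration scenario (`demo_scenario()`) uses 12 genes × 5
cis SNPs in LD blocks, 200 expression samples across two cell types, six
planted eQTLs, a 600/600 cohort with two disease SNPs (OR 1.4), and a
200,000-read coverage track with peaks at three eQTL SNPs — compact enough
to run end-to-end in well under a minute while exercising every stage at
the paper-scale permutation counts (320 eQTL permutations, 10,000 phenotype
permutations, 10,000 resampling iterations). The test suite's calibration
studies use larger designs (e.g. 200 genes × 3 SNPs × 10 replicates for
FDR calibration; 200 null cohorts for the type-I error of the set test)
chosen to make the binomial error bars on the measured rates decisively
smaller than the bands being checked.

# Known limitations

* The exhaustive selection bound ($k \le 10$) is a hard error; loci with
  more significant SNPs must be pre-thinned (the pipeline takes the 10
  smallest p values).
* λ over small SNP sets is reported but noisy; interpret alongside the
  permutation p. Because λ₁₀₀₀ is affine in λ, a deflated λ (< 1) in a
  cohort smaller than 1000/1000 is amplified downwards and can yield a
  λ₁₀₀₀ below zero; the value is reported exactly as the formula gives it.
* The independence filter is greedy and order-dependent by design
  (deterministic and auditable); clumping-style or iterative-removal
  variants are not implemented.
* The allelic χ² test carries no covariate adjustment, matching the
  standard allelic GWAS statistic it mirrors.
* Empirical p values of 0 are reported as computed (with the conservative
  variant and the `<1/B` string); downstream BH adjustment of exact zeros
  is as conservative as the permutation count allows.
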