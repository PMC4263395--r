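---
title: "Scanning for plastic alleles: methods behind vargwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for plastic alleles: methods behind vargwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Collections of inbred plant accessions sampled across a species' native
range carry climate values of their sampling sites as "phenotypes". Because
allele frequencies and climate both follow geography, mean-effect GWAS on
such data is strongly confounded with population structure, and mixed-model
correction then removes much of the locally adaptive signal along with the
confounding. `vargwas` implements the complementary strategy: screen for
*plastic* alleles, alleles whose carriers occupy a **broader range** of an
environmental variable than the alternative allele. Such alleles segregate
across the whole population rather than following a cline, so they are less
confounded with structure, and they leave a variance signature rather than a
mean signature.

## Model

Let $y$ be the raw phenotype (e.g. temperature seasonality, the SD of
temperature in % of its mean at the sampling site). The scan response is
built in two steps:

1. **Rank-based inverse normal transform.**
   $z_i = \Phi^{-1}\{(r_i - c)/(n - 2c + 1)\}$ with ranks $r_i$ (average
   ranks for ties) and offset $c = 3/8$ (Blom). The offset is configurable;
   Blom is the common default and the choice is immaterial at the sample
   sizes the scan needs. Any monotone re-expression of the raw phenotype
   leaves $z$ unchanged.
2. **Squaring.** $y^*_i = z_i^2$. Accessions in either tail of the
   phenotype distribution get large $y^*$; a locus whose minor allele
   spreads its carriers across the environmental range therefore shifts the
   *mean* of $y^*$ in the carrier group. Variance-heterogeneity detection
   reduces to a mean test on $y^*$.

The per-SNP model is the linear mixed model
$$y^* = \mu + \beta g + u + e,\qquad u \sim N(0, \sigma_g^2 S),\quad
  e \sim N(0, \sigma_e^2 I),$$
with $g$ coded 0/2 (inbred homozygotes; heterozygous calls are treated as
missing, and missing calls are mean-imputed at standardization time).

## The HEM kinship

The polygenic covariance $S$ is not the plain GRM but a weighted one,
obtained from a whole-genome ridge regression (SNP-BLUP) under the
heteroscedastic effects model (HEM):

* Standardize genotypes: $z_{ij} = (g_{ij} - 2p_j)/(2\sqrt{p_j(1-p_j)})$
  (for 0/2 inbred coding the genotypic variance is $4p(1-p)$).
* Fit $\hat\beta = (Z'Z + \lambda I)^{-1} Z' (y - \bar y)$ with
  $\lambda = \hat\sigma_e^2/\hat\sigma_b^2$ estimated by REML on the
  equivalent random-effect model via the eigendecomposition of $ZZ'$. The
  $n \times n$ dual form is used when $m > n$; the primal and dual routes
  agree to numerical precision and both are exposed for cross-checking.
* Weight each SNP by its shrinkage-corrected squared effect
  $d_j = \hat\beta_j^2/(1 - h_{jj})$, where
  $h_{jj} = [(Z'Z+\lambda I)^{-1}Z'Z]_{jj}$ is the coefficient leverage
  (bounded in $[0,1)$ for $\lambda > 0$ by the eigenvalue argument
  $s/(s+\lambda)$). Any constant factor in $d$ cancels in the next step, so
  conventions differing by a factor of 2 are inert.
* $S = Z\,\mathrm{diag}(d)\,Z'$, rescaled to mean diagonal 1 so that
  $\sigma_g^2$ is comparable across weightings.

**Which response drives the ridge?** The package fits the SNP-BLUP on the
normal scores $z$, not on $y^*$. The kinship is meant to describe
relatedness plus the SNPs' effects on the *phenotype*; building it from the
squared scores instead would put the variance-test signal itself into the
null covariance — in our simulations the planted variance locus then drops
from rank 1 to the mid-hundreds and the genomic-control factor deflates to
about 0.75 — so the phenotype-scale scores are the right ridge response.
`snp_blup()` itself is response-agnostic for users who want either variant.

When the ridge REML finds no genomic variance at all (a boundary estimate
$\hat\sigma_b^2 = 0$, common for a pure-noise response), the package uses
the infinite-shrinkage limit: relative effect sizes, and hence the rescaled
weights, remain well defined, and a warning is emitted.

A frequency-weighted IBS kinship ($S = ZZ'/m$, the conventional GRM) is
provided for mean-effect trait associations (`lmm_assoc()`), matching
standard mixed-model GWAS practice.

## Testing, genomic control and the Gamma guard

The null model (no SNP term) is fitted once by REML, profiling the
likelihood over the heritability ratio $h^2 = \sigma_g^2/(\sigma_g^2 +
\sigma_e^2)$ on the eigenbasis of $S$; the $h^2 = 0$ boundary is always
evaluated and wins ties, so a likelihood flat in the split (e.g. $S = I$)
deterministically returns $\hat\sigma_g^2 = 0$ with a note. Each SNP is then
tested with the score statistic
$$T^2 = \frac{(g_c' \hat V^{-1} y_c)^2}{g_c' \hat V^{-1} g_c}
  \sim \chi^2_1,$$
where $g_c, y_c$ are the genotype and response centered at their GLS means
and $\hat V = \hat\sigma_g^2 S + \hat\sigma_e^2 I$ is shared across all SNPs
(no per-SNP refit — this is what makes the scan cheap). The reported effect
is $(g_c'\hat V^{-1}y_c)/(g_c'\hat V^{-1}g_c)$, positive when the allele
coded 2 associates with larger $y^*$, with SE
$1/\sqrt{g_c'\hat V^{-1}g_c}$; with known $V$ the statistic coincides with
the GLS Wald statistic.

Genomic control divides every statistic by
$\lambda_{GC} = \mathrm{median}(T^2)/0.4549$ (the $\chi^2_1$ median). The
factor is applied **as computed** — values below 1 deflate — because the
scan is reported before and after GC; a floor at 1 is available by flag.
SNPs with MAF below 0.05 are excluded (a SNP at exactly 0.05 is kept), and
the genome-wide threshold is Bonferroni $\alpha/m$.

Because $y^*$ is positive and right-skewed, significant hits are re-checked
with a Gamma GLM (log link) of $y^*$ on the genotype; hits without support
there may be driven by a handful of low-frequency carriers and are flagged,
not removed. Zeros in $y^*$ are floored at $10^{-8}$ to keep the response
strictly positive; the link is a package choice (the family alone does not
fix it) and keeps a multiplicative variance interpretation.

## Downstream analyses

* **LD candidate screen:** all SNPs within ±100 kb of a leading SNP with
  $r^2 > 0.8$ (squared Pearson correlation of the 0/2 codes, which equals
  haplotype $r^2$ for inbred lines; pairwise-complete deletion for missing
  calls). Both cutoffs are parameters; hits nest as the $r^2$ threshold
  decreases and the window widens.
* **Focal-SNP trait association:** REML mixed model with the IBS kinship,
  optional covariate and genotype-by-covariate interaction, Wald t-tests
  with $n - p$ degrees of freedom (with $K = I$ the fit reduces exactly to
  OLS). A batch mode over a many-phenotype table attaches a
  Benjamini–Hochberg FDR column — BH is the standard choice where no
  specific FDR procedure is mandated.
* **TE methylation metaprofiles:** per-site CHH levels (methylated/total,
  zero-coverage sites excluded, no smoothing) are binned by distance to the
  nearer TE border, pooled over strands and TEs, and averaged in 100-bp
  windows sliding by 50 bp (the window is standard; the step is a package
  choice), truncated 5 kb from the border and at the TE midpoint so each
  site counts once. Curves are kept per border (the two halves of the
  mirror-style metaplot in which TE edges are aligned) along with the
  pooled curve; windows without sites are `NA`, never 0. An accession is
  called *knockout-like* when its mean TE-body CHH level falls below half
  the cohort median — an explicit, deterministic stand-in for what is
  otherwise a visual pattern match, and deliberately scale-free. Enrichment
  of knockout-like status between genotype groups uses Fisher's exact test;
  heterogeneity of methylation levels uses the Brown–Forsythe test (ANOVA
  on absolute deviations from group medians).
* **Heat-stress statistics:** survivor counts across replicate experiments
  are modeled by a Gaussian-family log-link GLM with experiment and
  genotype effects and $\log(\text{total})$ offset, so genotype
  coefficients are log survival-rate ratios. This family/link combination
  reproduces the described analysis exactly (with one experiment and two
  genotypes the fold equals the raw rate ratio); a Poisson-offset
  alternative is available by flag for users who prefer the conventional
  count model. Zero-survivor cells error unless an epsilon policy is
  enabled. Root-growth comparisons use a pooled-variance one-sided t-test
  (Welch by flag).

## The synthetic-data generator

`sim_*` functions generate every input the pipeline consumes, with the
statistical structure the analyses assume:

* **Genotypes:** Balding–Nichols model — ancestral frequencies
  Uniform(0.05, 0.95), subpopulation frequencies
  Beta$(p(1-F)/F, (1-p)(1-F)/F)$ with $F = F_{ST}$, inbred genotypes
  $2\times$Bernoulli, round-robin subpopulation assignment (deterministic).
  Planted variance loci get their configured frequency in every
  subpopulation, emulating a plastic allele spread across strata.
* **Phenotypes:** subpopulation mean shifts (structure confounding) plus
  optional additive effects, with residual SD multiplied by the configured
  ratio for minor-allele homozygotes at variance loci. The multiplicative
  SD model keeps the induced $y^*$ effects positive, matching the
  one-sided nature of the scan. For calibration studies the package uses
  subpopulation shifts drawn on the residual-SD scale (standard-normal
  shifts), strong-but-plausible confounding chosen a priori.
* **Methylomes:** wild-type-like and knockout-like groups at TE-body CHH
  levels 0.20 and 0.02 (typical wild-type TE-body CHH versus near-absent
  knockout methylation), low background outside TE bodies, Beta per-site
  noise (SD 0.05), Poisson(20) coverage truncated at 1 read.
* **Stress tables:** Binomial survivor counts with log-normal
  experiment-specific base rates around 0.40 and a default 1.6-fold carrier
  effect, six experiments of 30 plants per genotype.

Each generator is a pure function of its configuration and an integer seed;
seeding saves and restores the caller's RNG state, and derived streams use
fixed integer offsets of the configured seed (R's RNG offers no splittable
counter, so deterministic offsets replace a counter-based splitting scheme).

What the generator does **not** emulate: linkage disequilibrium beyond
duplicated columns (sites are exchangeable given the subpopulation
frequencies), coalescent genealogies, genotyping error, climate-raster
autocorrelation, or read-level methylation artefacts. Passing the test
suite therefore demonstrates correctness of the statistical machinery under
the assumed generative model, not robustness to every property of real
data — in particular, real LD makes "top-SNP" resolution optimistic here.

## Numerical choices and degenerate inputs

* REML is a 1-D profile over $h^2 \in [10^{-6}, 1-10^{-6}]$ via Brent
  search (tolerance $10^{-9}$) plus an explicit boundary evaluation;
  eigenvalues are clipped at 0 and kinships are accepted while their
  smallest eigenvalue exceeds $-10^{-8}\,\mathrm{tr}(S)/n$.
* Constant SNPs are an error in single tests and an `NA`-with-warning in
  scan mode; monomorphic SNPs must be removed (by the MAF filter) before
  standardization, and division-by-zero errors name the offending SNP.
* Test-suite and calibration problem sizes — 500–1000 accessions, 5000
  SNPs, 5 subpopulations, 10–20 replicate seeds — are chosen so that the
  asymptotics the score test relies on are comfortably reached while a full
  check runs in minutes on a laptop.

## Known limitations

Single-SNP variance signals only (no haplotype or multi-locus models); the
HEM weights are a single update step, not iterated to convergence;
imputation is mean-fill only; multi-allelic variants are skipped; the
knockout-like rule is a declared convention, not an inference; and the scan
has low power for minor alleles associated with *lower* variance, which is
inherent to the one-tailed variance signature it targets.
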