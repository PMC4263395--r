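Package: vargwas
Title: Variance-Heterogeneity Genome-Wide Association Scans for
    Environmental Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome-wide scans for "plastic" alleles whose carriers tolerate
    a broader range of an environmental variable, detected as genetic
    variance-heterogeneity. Phenotypes are rank-transformed to normal scores
    and the squared scores analysed with a linear mixed model whose polygenic
    covariance is a heteroscedastic-effects-model (HEM) kinship built from a
    whole-genome ridge regression (SNP-BLUP). Includes the per-SNP score
    test with genomic control and a Gamma-GLM guard against low-frequency
    artefacts, LD-based candidate screening, kinship-corrected single-locus
    trait association with genotype-by-covariate interactions,
    transposable-element CHH-methylation metaprofiles with enrichment and
    variance-heterogeneity tests, heat-stress survival statistics, and a
    structured-population synthetic-data generator exercising the full
    pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    rtracklayer,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
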