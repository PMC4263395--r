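#' Full variance-heterogeneity adaptability scan
#'
#' End-to-end pipeline: align phenotype and genotypes, exclude SNPs with
#' MAF below `maf`, inverse-normal-transform the phenotype, build the
#' kinship (for `"hem"`, the SNP-BLUP ridge is fitted on the normal scores
#' `z`, so the kinship reflects the SNPs' effects on the phenotype itself;
#' the scan then tests the squared scores `y* = z^2`), run the score test
#' per SNP with genomic control, and optionally run the Gamma-GLM guard on
#' the Bonferroni-significant hits.
#'
#' @param G a [genotype_matrix].
#' @param pheno phenotype: data frame `(accession_id, value)` or a numeric
#'   vector already aligned with `G`'s accessions.
#' @param kinship `"hem"` (default), `"ibs"`, or a precomputed
#'   `kinship_matrix` aligned with `G`.
#' @param maf MAF exclusion threshold (default 0.05).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param gc,gc_floor genomic-control options (see [vgwas_scan]).
#' @param gamma run [gamma_check] on significant hits (default `TRUE`).
#' @param transform apply the inverse-normal transform and squaring
#'   (default `TRUE`); with `FALSE` the phenotype is squared around its mean
#'   scaled to unit variance first — escape hatch for pre-transformed input.
#' @return a `vgwas_scan` data frame with extra columns `significant`
#'   (p_gc below the Bonferroni threshold) and `gamma_p` (NA for
#'   non-significant SNPs); attributes `lambda_gc`, `threshold`, `null`,
#'   `transform` and `kinship`.
#' @export
adaptability_scan <- function(G, pheno, kinship = "hem", maf = 0.05,
                              alpha = 0.05, gc = TRUE, gc_floor = FALSE,
                              gamma = TRUE, transform = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.data.frame(pheno)) {
    al <- align_phenotype(G, pheno)
    G <- al$G; y <- al$y
  } else {
    y <- as.numeric(pheno)
    if (length(y) != nrow(G$codes))
      stop("phenotype length does not match accessions", call. = FALSE)
  }
  Gf <- maf_filter(G, maf)
  tr <- if (transform) adaptability_response(y)
        else { zc <- (y - mean(y)) / stats::sd(y); list(z = zc, ystar = zc^2) }
  S <- if (inherits(kinship, "kinship_matrix")) kinship
       else build_kinship(Gf, tr$z, method = kinship)
  sc <- vgwas_scan(Gf, tr$ystar, S, gc = gc, gc_floor = gc_floor)
  thr <- bonferroni_threshold(sum(!is.na(sc$p_gc)), alpha)
  sc$significant <- !is.na(sc$p_gc) & sc$p_gc < thr
  sc$gamma_p <- NA_real_
  if (gamma && any(sc$significant)) {
    for (i in which(sc$significant))
      sc$gamma_p[i] <- gamma_check(tr$ystar, Gf$codes[, i])$p
  }
  attr(sc, "threshold") <- thr
  attr(sc, "transform") <- tr
  attr(sc, "kinship") <- attr(S, "kind") %||% "supplied"
  sc
}
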