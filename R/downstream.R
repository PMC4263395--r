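#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the 0/2 genotype codes; for inbred lines
#' this equals the haplotype r-squared. Pairs with a missing call in either
#' SNP are dropped.
#'
#' @param g1,g2 genotype columns over the same accessions.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- as.numeric(g1[ok]); g2 <- as.numeric(g2[ok])
  if (length(g1) < 2 || stats::var(g1) == 0 || stats::var(g2) == 0)
    stop("LD undefined for constant genotype vectors", call. = FALSE)
  stats::cor(g1, g2)^2
}

#' Screen for candidate SNPs in LD with a leading SNP
#'
#' Reports all SNPs on the leading SNP's chromosome within a +/- `window` bp
#' interval (inclusive, measured from the leading position) whose r-squared
#' with the lead exceeds `r2_min`, excluding the lead itself.
#'
#' @param G a [genotype_matrix].
#' @param lead_snp SNP id present in `G`, or `"chrom:pos"`.
#' @param window half-width of the interval in bp (default 100000).
#' @param r2_min LD threshold (default 0.8, strict `>`).
#' @return data frame sorted by position: `snp_id`, `chrom`, `pos`, `r2`,
#'   `distance` (bp from the lead).
#' @export
candidate_screen <- function(G, lead_snp, window = 1e5, r2_min = 0.8) {
  stopifnot(inherits(G, "genotype_matrix"))
  i <- match(lead_snp, G$snps$snp_id)
  if (is.na(i))
    i <- match(lead_snp, paste(G$snps$chrom, G$snps$pos, sep = ":"))
  if (is.na(i)) stop("leading SNP not found: ", lead_snp, call. = FALSE)
  lead <- G$snps[i, ]
  cand <- which(G$snps$chrom == lead$chrom &
                  abs(G$snps$pos - lead$pos) <= window)
  cand <- setdiff(cand, i)
  g0 <- G$codes[, i]
  hits <- lapply(cand, function(j) {
    r2 <- tryCatch(pairwise_r2(g0, G$codes[, j]), error = function(e) NA_real_)
    if (!is.na(r2) && r2 > r2_min)
      data.frame(snp_id = G$snps$snp_id[j], chrom = G$snps$chrom[j],
                 pos = G$snps$pos[j], r2 = r2,
                 distance = abs(G$snps$pos[j] - lead$pos),
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), r2 = numeric(), distance = integer(),
                      stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

#' Kinship-corrected association of a focal SNP with a trait
#'
#' REML linear mixed model
#' \eqn{y = \mu + \beta g\; (+ \gamma c + \delta\, g c) + u + e} with
#' \eqn{u \sim N(0, \sigma_g^2 K)}; Wald t-tests (df = n - p) on the genotype
#' effect and, if requested, on the genotype-by-covariate interaction. With
#' `K = I` the fit reduces exactly to ordinary least squares.
#'
#' @param pheno numeric trait vector.
#' @param g genotype column (0/2 codes; NA mean-imputed).
#' @param K kinship matrix.
#' @param covariate optional numeric covariate aligned with `pheno`.
#' @param interaction fit and test the genotype-by-covariate interaction.
#' @return list with `effect`, `se`, `p`, variance components, and if
#'   requested `interaction_effect`, `interaction_se`, `interaction_p`.
#' @export
lmm_assoc <- function(pheno, g, K, covariate = NULL, interaction = FALSE) {
  y <- as.numeric(pheno)
  g <- as.numeric(g)
  if (any(is.na(g))) g[is.na(g)] <- mean(g, na.rm = TRUE)
  X <- cbind(`(Intercept)` = 1, g = g)
  if (!is.null(covariate)) {
    X <- cbind(X, covariate = as.numeric(covariate))
    if (interaction) X <- cbind(X, `g:covariate` = g * as.numeric(covariate))
  } else if (interaction) {
    stop("interaction requested without a covariate", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X))
    stop("singular design: genotype confounded with covariate", call. = FALSE)
  validate_kinship(K)
  eig <- eigen(as.matrix(K), symmetric = TRUE)
  fit <- reml_eigen(y, X, eig)
  w <- 1 / fit$xi
  XtWX <- crossprod(fit$tX, fit$tX * w)
  vb <- fit$s2 * solve(XtWX)
  se <- sqrt(diag(vb))
  tval <- fit$beta / se
  df <- fit$n - fit$p
  pv <- 2 * stats::pt(-abs(tval), df = df)
  out <- list(effect = fit$beta[["g"]], se = se[["g"]], p = pv[["g"]],
              coefficients = fit$beta, sigma_g2 = fit$sigma_g2,
              sigma_e2 = fit$sigma_e2, df = df)
  if (interaction) {
    out$interaction_effect <- fit$beta[["g:covariate"]]
    out$interaction_se <- se[["g:covariate"]]
    out$interaction_p <- pv[["g:covariate"]]
  }
  out
}

#' Batch association of a focal SNP across many phenotypes
#'
#' Runs [lmm_assoc] for every phenotype column and attaches a
#' Benjamini-Hochberg FDR column across phenotypes.
#'
#' @param pheno_table data frame: first column `accession_id`, remaining
#'   columns one phenotype each.
#' @param g named genotype vector (0/2) covering the accessions.
#' @param K kinship matrix with accession-id dimnames.
#' @return data frame with one row per phenotype: `phenotype`, `n`, `effect`,
#'   `se`, `p`, `fdr`.
#' @export
assoc_batch <- function(pheno_table, g, K) {
  acc <- as.character(pheno_table[[1]])
  res <- lapply(names(pheno_table)[-1], function(ph) {
    y <- as.numeric(pheno_table[[ph]])
    ok <- is.finite(y) & acc %in% names(g) & acc %in% rownames(K)
    ids <- acc[ok]
    r <- tryCatch(
      lmm_assoc(y[ok], g[ids], kinship_matrix(K[ids, ids], attr(K, "kind") %||% "file")),
      error = function(e) NULL)
    data.frame(phenotype = ph, n = sum(ok),
               effect = r$effect %||% NA_real_, se = r$se %||% NA_real_,
               p = r$p %||% NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}
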