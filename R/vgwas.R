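#' Fit the null mixed model of the variance-heterogeneity scan
#'
#' REML fit of \eqn{y^* = \mu + u + e} with \eqn{u \sim N(0, \sigma_g^2 S)}
#' and \eqn{e \sim N(0, \sigma_e^2 I)}, via the eigendecomposition of the
#' kinship and a 1-D profile over the variance ratio. \eqn{\hat\sigma_g^2}
#' may land on the 0 boundary; a likelihood that is flat in the split (e.g.
#' `S = I`) returns \eqn{\hat\sigma_g^2 = 0} with a note.
#'
#' @param ystar squared normal scores (from [adaptability_response]), one per
#'   accession in kinship order.
#' @param S kinship matrix (symmetric PSD), e.g. from [build_kinship].
#' @return object of class `null_model_fit`: `mu` (GLS intercept),
#'   `sigma_g2`, `sigma_e2`, `h2`, `reml_loglik`, plus the eigendecomposition
#'   of `S` reused by [score_test] and [vgwas_scan].
#' @export
fit_null <- function(ystar, S) {
  ystar <- as.numeric(ystar)
  if (any(!is.finite(ystar))) stop("ystar must be finite", call. = FALSE)
  validate_kinship(S)
  if (length(ystar) != nrow(S))
    stop("length(ystar) must match the kinship dimension", call. = FALSE)
  eig <- eigen(as.matrix(S), symmetric = TRUE)
  fit <- reml_eigen(ystar, matrix(1, length(ystar), 1), eig)
  structure(list(mu = fit$beta[1], sigma_g2 = fit$sigma_g2,
                 sigma_e2 = fit$sigma_e2, h2 = fit$h2,
                 reml_loglik = fit$loglik, eig = eig, n = fit$n),
            class = "null_model_fit")
}

#' Null model with known variance components
#'
#' Builds a `null_model_fit` with supplied variance components instead of
#' estimating them by REML — useful for oracle checks with a known
#' covariance (e.g. `V = I`) and for reusing externally estimated
#' components.
#'
#' @param S kinship matrix.
#' @param sigma_g2,sigma_e2 variance components of \eqn{V = \sigma_g^2 S +
#'   \sigma_e^2 I}.
#' @param mu intercept; default 0.
#' @return a `null_model_fit`.
#' @export
null_model <- function(S, sigma_g2, sigma_e2, mu = 0) {
  validate_kinship(S)
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0", call. = FALSE)
  eig <- eigen(as.matrix(S), symmetric = TRUE)
  structure(list(mu = mu, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = sigma_g2 / (sigma_g2 + sigma_e2),
                 reml_loglik = NA_real_, eig = eig, n = nrow(S)),
            class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf("null_model_fit: mu = %.4f, sigma_g2 = %.4f, sigma_e2 = %.4f (h2 = %.3f)\n",
              x$mu, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

# rotated inverse-variance weights of V = sg2 * S + se2 * I
null_weights <- function(null) {
  v <- null$sigma_g2 * pmax(null$eig$values, 0) + null$sigma_e2
  if (any(v <= 0)) stop("null covariance not positive definite", call. = FALSE)
  1 / v
}

#' Score test of one SNP on the squared response
#'
#' With \eqn{\hat V} from the null fit and genotype/response centered by
#' their \eqn{\hat V^{-1}}-weighted (GLS) means,
#' \deqn{T^2 = (g_c' \hat V^{-1} y_c)^2 / (g_c' \hat V^{-1} g_c)}
#' is referred to a chi-square distribution with 1 degree of freedom. The
#' reported effect is \eqn{(g_c'\hat V^{-1} y_c)/(g_c'\hat V^{-1} g_c)} with
#' standard error \eqn{1/\sqrt{g_c'\hat V^{-1} g_c}}; a positive effect means
#' the allele coded 2 is associated with larger \eqn{y^*} (broader range).
#'
#' @param g genotype column (0/2 codes, NA mean-imputed), same accession
#'   order as the null fit.
#' @param ystar squared normal scores used for the null fit.
#' @param null a `null_model_fit`.
#' @return list with `chi2`, `p`, `effect`, `se`.
#' @export
score_test <- function(g, ystar, null) {
  stopifnot(inherits(null, "null_model_fit"))
  g <- as.numeric(g)
  if (any(is.na(g))) g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (stats::var(g) == 0)
    stop("constant genotype: score test undefined", call. = FALSE)
  w <- null_weights(null)
  U <- null$eig$vectors
  t1 <- crossprod(U, rep(1, length(g)))
  tg <- crossprod(U, g)
  ty <- crossprod(U, ystar)
  s11 <- sum(w * t1^2)
  tgc <- tg - t1 * (sum(w * t1 * tg) / s11)
  tyc <- ty - t1 * (sum(w * t1 * ty) / s11)
  den <- sum(w * tgc^2)
  num <- sum(w * tgc * tyc)
  chi2 <- num^2 / den
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       effect = num / den, se = 1 / sqrt(den))
}

#' Genome-wide variance-heterogeneity scan
#'
#' Applies [score_test] to every SNP against one shared null fit (no per-SNP
#' refit), then attaches genomic-control-adjusted statistics.
#'
#' @param G MAF-filtered [genotype_matrix].
#' @param ystar squared normal scores aligned with `G`'s accessions.
#' @param S kinship matrix; alternatively pass a prefitted `null_model_fit`
#'   via `null`.
#' @param null optional `null_model_fit` (overrides `S`).
#' @param gc apply genomic control (default `TRUE`).
#' @param gc_floor floor the inflation factor at 1 (default `FALSE`: the
#'   estimated factor is applied as computed).
#' @return data frame of class `vgwas_scan` with one row per SNP: `snp_id`,
#'   `chrom`, `pos`, `maf`, `chi2`, `p_raw`, `chi2_gc`, `p_gc`, `effect`,
#'   `se`; `lambda_gc` is attached as an attribute. SNPs whose test fails
#'   (e.g. constant after imputation) get NA statistics and a warning.
#' @export
vgwas_scan <- function(G, ystar, S = NULL, null = NULL, gc = TRUE,
                       gc_floor = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(null)) {
    if (is.null(S)) stop("supply a kinship 'S' or a prefitted 'null'", call. = FALSE)
    null <- fit_null(ystar, S)
  }
  codes <- G$codes
  n <- nrow(codes); m <- ncol(codes)
  Gn <- matrix(as.numeric(codes), n, m)
  if (anyNA(Gn)) {
    mu_j <- colMeans(Gn, na.rm = TRUE)
    idx <- which(is.na(Gn), arr.ind = TRUE)
    Gn[idx] <- mu_j[idx[, 2]]
  }
  w <- null_weights(null)
  U <- null$eig$vectors
  t1 <- drop(crossprod(U, rep(1, n)))
  ty <- drop(crossprod(U, ystar))
  s11 <- sum(w * t1^2)
  tyc <- ty - t1 * (sum(w * t1 * ty) / s11)
  TG <- crossprod(U, Gn)
  gmeans <- drop(crossprod(w * t1, TG)) / s11
  TGc <- TG - outer(t1, gmeans)
  den <- colSums(w * TGc^2)
  num <- drop(crossprod(w * TGc, tyc))
  bad <- den <= 1e-12
  if (any(bad)) {
    warning(sum(bad), " SNP(s) constant after imputation; statistics set NA",
            call. = FALSE)
    den[bad] <- NA_real_
  }
  chi2 <- num^2 / den
  out <- data.frame(
    snp_id = G$snps$snp_id, chrom = G$snps$chrom, pos = G$snps$pos,
    maf = G$snps$maf, chi2 = chi2,
    p_raw = stats::pchisq(chi2, 1, lower.tail = FALSE),
    effect = num / den, se = 1 / sqrt(den), stringsAsFactors = FALSE)
  if (gc) {
    adj <- genomic_control(chi2[!is.na(chi2)], floor_at_1 = gc_floor)
    out$chi2_gc <- chi2 / adj$lambda_gc
    out$p_gc <- stats::pchisq(out$chi2_gc, 1, lower.tail = FALSE)
    attr(out, "lambda_gc") <- adj$lambda_gc
  } else {
    out$chi2_gc <- out$chi2
    out$p_gc <- out$p_raw
    attr(out, "lambda_gc") <- NA_real_
  }
  attr(out, "null") <- null[c("mu", "sigma_g2", "sigma_e2", "h2", "reml_loglik")]
  class(out) <- c("vgwas_scan", class(out))
  out
}

#' Genomic control of 1-df score statistics
#'
#' The inflation factor is the median observed statistic divided by the
#' chi-square(1) median (0.45494); every statistic is divided by it. The
#' factor is applied as computed (values below 1 deflate) unless
#' `floor_at_1 = TRUE`.
#'
#' @param chi2 vector of 1-df chi-square statistics (>= 100 recommended).
#' @param floor_at_1 floor the factor at 1.
#' @return list with `lambda_gc` and `adjusted` (`chi2 / lambda_gc`).
#' @export
genomic_control <- function(chi2, floor_at_1 = FALSE) {
  chi2 <- as.numeric(chi2)
  if (length(chi2) == 0) stop("empty statistic vector", call. = FALSE)
  lambda <- stats::median(chi2, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
  if (floor_at_1) lambda <- max(lambda, 1)
  list(lambda_gc = lambda, adjusted = chi2 / lambda)
}

#' Bonferroni-corrected genome-wide significance threshold
#'
#' @param m_tested number of SNPs tested (after MAF filtering).
#' @param alpha family-wise error rate; default 0.05.
#' @return per-test p-value threshold `alpha / m_tested`.
#' @export
bonferroni_threshold <- function(m_tested, alpha = 0.05) {
  stopifnot_scalar_number(m_tested, "m_tested")
  if (m_tested < 1) stop("'m_tested' must be >= 1", call. = FALSE)
  alpha / m_tested
}

#' Gamma-GLM guard for significant variance-heterogeneity hits
#'
#' The squared response is positive and right-skewed, so a Gamma generalized
#' linear model with log link of \eqn{y^*} on the genotype gives a check that
#' is robust to the chi-square-like response shape: significant scan hits
#' whose Gamma-GLM genotype coefficient is not supported may be driven by a
#' handful of low-frequency carriers. Values of \eqn{y^*} below `epsilon`
#' are raised to `epsilon` to keep the response strictly positive.
#'
#' @param ystar squared normal scores.
#' @param g genotype column (0/2; non-constant).
#' @param epsilon positivity floor, default `1e-8`.
#' @return list with `p` (Wald p-value for the genotype coefficient),
#'   `coef`, `se`, `converged`.
#' @export
gamma_check <- function(ystar, g, epsilon = 1e-8) {
  g <- as.numeric(g)
  if (any(is.na(g))) g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (stats::var(g) == 0) stop("constant genotype", call. = FALSE)
  y <- pmax(as.numeric(ystar), epsilon)
  fit <- tryCatch(
    stats::glm(y ~ g, family = stats::Gamma(link = "log")),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(stats::glm(y ~ g, family = stats::Gamma(link = "log")))
    })
  if (is.null(fit) || !fit$converged)
    return(list(p = NA_real_, coef = NA_real_, se = NA_real_, converged = FALSE))
  cf <- summary(fit)$coefficients
  list(p = cf["g", 4], coef = cf["g", 1], se = cf["g", 2], converged = TRUE)
}

#' Manhattan and QQ plots for a scan
#'
#' @param scan a `vgwas_scan`.
#' @param threshold optional p-value threshold drawn as a horizontal line.
#' @param ... passed to [graphics::plot].
#' @return the input, invisibly.
#' @export
manhattan_plot <- function(scan, threshold = NULL, ...) {
  chroms <- unique(scan$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(scan$pos[scan$chrom == ch]), 0)))
  x <- scan$pos + offs[match(scan$chrom, chroms)]
  col <- (match(scan$chrom, chroms) %% 2) + 1
  graphics::plot(x, -log10(scan$p_gc), pch = 20, col = c("grey40", "steelblue")[col],
                 xlab = "genome position", ylab = expression(-log[10](p[GC])), ...)
  if (!is.null(threshold)) graphics::abline(h = -log10(threshold), lty = 2)
  invisible(scan)
}

#' @rdname manhattan_plot
#' @export
qq_plot <- function(scan, ...) {
  p <- sort(scan$p_gc[!is.na(scan$p_gc)])
  exp_p <- stats::ppoints(length(p))
  graphics::plot(-log10(exp_p), -log10(p), pch = 20,
                 xlab = expression(Expected - log[10](p)),
                 ylab = expression(Observed - log[10](p)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(scan)
}
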