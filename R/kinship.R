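#' Standardize 0/2 genotype codes by allele frequency
#'
#' For inbred lines coded 0/2 the genotype variance at allele frequency
#' \eqn{p} is \eqn{4p(1-p)}, so each SNP column is transformed as
#' \eqn{z = (g - 2p) / (2\sqrt{p(1-p)})}. Missing calls are mean-imputed
#' (they contribute exactly 0 after centering).
#'
#' @param G a [genotype_matrix] with no monomorphic SNPs (run [maf_filter]
#'   first).
#' @return object of class `standardized_genotypes`: list with `Z` (n x m
#'   numeric matrix, column means 0) and `allele_freqs` (per-SNP sample
#'   alt-allele frequency).
#' @export
standardize <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  codes <- G$codes
  p <- colMeans(codes, na.rm = TRUE) / 2
  mono <- !is.finite(p) | p <= 0 | p >= 1
  if (any(mono))
    stop("monomorphic SNP(s) cannot be standardized: ",
         paste(utils::head(G$snps$snp_id[mono], 5), collapse = ", "),
         call. = FALSE)
  Z <- sweep(codes, 2, 2 * p)              # NA stays NA
  Z[is.na(Z)] <- 0                         # mean imputation after centering
  Z <- sweep(Z, 2, 2 * sqrt(p * (1 - p)), "/")
  structure(list(Z = Z, allele_freqs = p), class = "standardized_genotypes")
}

# ---------------------------------------------------------------------------
# REML machinery shared by snp_blup, fit_null and lmm_assoc.
#
# Model: y = X beta + u + e,  u ~ N(0, sg2 * S), e ~ N(0, se2 * I).
# Parameterized by h2 = sg2 / (sg2 + se2); given the eigendecomposition
# S = U L U', the rotated model is independent with variances
# s2 * (h2 * l_i + 1 - h2). h2 is profiled out by 1-D optimization of the
# REML log-likelihood; the h2 = 0 boundary is always evaluated and wins ties
# (so a flat likelihood, e.g. S = I, returns sg2 = 0).
reml_eigen <- function(y, X, eig, tol = 1e-8) {
  n <- length(y); p <- ncol(X)
  lam <- pmax(eig$values, 0)
  ty <- crossprod(eig$vectors, y)
  tX <- crossprod(eig$vectors, X)
  profile <- function(h2) {
    xi <- h2 * lam + (1 - h2)
    w <- 1 / xi
    XtWX <- crossprod(tX, tX * w)
    beta <- solve(XtWX, crossprod(tX, ty * w))
    r <- ty - tX %*% beta
    R <- sum(w * r^2)
    s2 <- R / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(xi)) +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
    list(h2 = h2, beta = drop(beta), s2 = s2, loglik = as.numeric(ll))
  }
  opt <- stats::optimize(function(h2) -profile(h2)$loglik,
                         interval = c(1e-6, 1 - 1e-6), tol = 1e-9)
  cand <- profile(opt$minimum)
  bound <- profile(0)
  fit <- if (bound$loglik >= cand$loglik - tol) {
    if (abs(bound$loglik - cand$loglik) <= tol && opt$minimum > 0.01)
      message("REML likelihood flat in the variance split; returning sigma_g2 = 0")
    bound
  } else cand
  xi <- fit$h2 * lam + (1 - fit$h2)
  list(h2 = fit$h2, beta = fit$beta,
       sigma_g2 = fit$h2 * fit$s2, sigma_e2 = (1 - fit$h2) * fit$s2,
       s2 = fit$s2, loglik = fit$loglik, eig = eig, xi = xi,
       ty = ty, tX = tX, n = n, p = p)
}

#' Whole-genome ridge regression (SNP-BLUP)
#'
#' Fits \eqn{y = \mu + Zb + e} with a common ridge penalty
#' \eqn{\lambda = \sigma_e^2/\sigma_b^2}:
#' \eqn{\hat\beta = (Z'Z + \lambda I)^{-1} Z'(y - \bar y)} with per-SNP
#' coefficient leverage \eqn{h_{jj} = [(Z'Z + \lambda I)^{-1} Z'Z]_{jj}}.
#' When `lambda` is not supplied the variance components are estimated by
#' REML on the equivalent random-effect model via the eigendecomposition of
#' \eqn{ZZ'} and \eqn{\lambda = \hat\sigma_e^2/\hat\sigma_b^2}. For m > n the
#' n x n dual form is used.
#'
#' @param Z standardized genotype matrix (n x m) or a
#'   `standardized_genotypes` object.
#' @param y response vector (the squared normal scores for the
#'   variance-heterogeneity kinship).
#' @param lambda optional ridge penalty > 0.
#' @param method `"auto"` (dual if m > n), `"primal"` or `"dual"`; both give
#'   identical results and exist mainly for cross-checking.
#' @return object of class `ridge_fit`: list with `beta_hat`, `hat`
#'   (leverages in `[0,1)`), `lambda`, `sigma_b2`, `sigma_e2`.
#' @export
snp_blup <- function(Z, y, lambda = NULL, method = c("auto", "primal", "dual")) {
  method <- match.arg(method)
  if (inherits(Z, "standardized_genotypes")) Z <- Z$Z
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- ncol(Z)
  if (length(y) != n) stop("length(y) must equal nrow(Z)", call. = FALSE)
  yc <- y - mean(y)
  sigma_b2 <- sigma_e2 <- NA_real_
  if (is.null(lambda)) {
    eig <- eigen(tcrossprod(Z), symmetric = TRUE)
    fit <- reml_eigen(y, matrix(1, n, 1), eig)
    sigma_b2 <- fit$sigma_g2; sigma_e2 <- fit$sigma_e2
    if (sigma_b2 <= 0) {
      # boundary: no detectable genomic variance; in the infinite-shrinkage
      # limit the relative effect sizes (hence rescaled HEM weights) are
      # still well defined, so use a penalty far above the largest
      # eigenvalue of ZZ'
      warning("REML put all variance on the residual; using the ",
              "infinite-shrinkage limit for the ridge penalty", call. = FALSE)
      lambda <- 1e6 * max(eig$values)
    } else {
      lambda <- sigma_e2 / sigma_b2
    }
  } else {
    stopifnot_scalar_number(lambda, "lambda")
    if (lambda <= 0) stop("'lambda' must be > 0", call. = FALSE)
  }
  if (method == "auto") method <- if (m > n) "dual" else "primal"
  if (method == "primal") {
    ZtZ <- crossprod(Z)
    A <- solve(ZtZ + diag(lambda, m))
    beta <- drop(A %*% crossprod(Z, yc))
    hat <- diag(A %*% ZtZ)
  } else {
    eigK <- eigen(tcrossprod(Z), symmetric = TRUE)
    w <- 1 / (pmax(eigK$values, 0) + lambda)
    Ainv_yc <- eigK$vectors %*% (w * crossprod(eigK$vectors, yc))
    beta <- drop(crossprod(Z, Ainv_yc))
    AZ <- eigK$vectors %*% (w * crossprod(eigK$vectors, Z))
    hat <- colSums(Z * AZ)
  }
  structure(list(beta_hat = beta, hat = hat, lambda = lambda,
                 sigma_b2 = sigma_b2, sigma_e2 = sigma_e2),
            class = "ridge_fit")
}

#' Heteroscedastic-effects-model SNP weights
#'
#' Shrinkage-corrected squared SNP effects
#' \eqn{d_j = \hat\beta_j^2 / (1 - h_{jj})}: SNPs whose ridge effect survives
#' shrinkage get up-weighted in the kinship, so the polygenic covariance
#' reflects trait-relevant genome sharing.
#'
#' @param fit a `ridge_fit` from [snp_blup].
#' @return non-negative numeric vector of per-SNP weights.
#' @export
hem_weights <- function(fit) {
  stopifnot(inherits(fit, "ridge_fit"))
  if (any(fit$hat >= 1 - 1e-12))
    stop("degenerate leverage (h >= 1): lambda too small", call. = FALSE)
  fit$beta_hat^2 / (1 - fit$hat)
}

#' Wrap a matrix as a kinship object
#'
#' @param S square numeric matrix (symmetrized).
#' @param kind label, e.g. `"hem"`, `"ibs"` or `"file"`.
#' @return a `kinship_matrix`.
#' @export
kinship_matrix <- function(S, kind) {
  S <- (S + t(S)) / 2
  attr(S, "kind") <- kind
  class(S) <- c("kinship_matrix", class(S))
  S
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix (%s): %d x %d, mean diagonal %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Validate a kinship matrix
#'
#' Checks symmetry and positive semidefiniteness (smallest eigenvalue above
#' `-1e-8 * trace / n`).
#'
#' @param S square numeric matrix.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_kinship <- function(S) {
  if (nrow(S) != ncol(S)) stop("kinship must be square", call. = FALSE)
  if (max(abs(S - t(S))) >= 1e-10) stop("kinship not symmetric", call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= -1e-8 * sum(diag(S)) / nrow(S))
    stop("kinship not positive semidefinite", call. = FALSE)
  invisible(TRUE)
}

#' HEM-weighted genomic kinship
#'
#' \eqn{S = Z D Z'} with \eqn{D = \mathrm{diag}(d)}, rescaled so the mean
#' diagonal equals 1 (any common factor in `d` therefore cancels).
#'
#' @param Z standardized genotypes (matrix or `standardized_genotypes`).
#' @param d per-SNP weights from [hem_weights].
#' @param rescale rescale to mean diagonal 1 (default `TRUE`).
#' @return a `kinship_matrix` of kind `"hem"`.
#' @export
hem_kinship <- function(Z, d, rescale = TRUE) {
  if (inherits(Z, "standardized_genotypes")) Z <- Z$Z
  if (length(d) != ncol(Z)) stop("length(d) must equal ncol(Z)", call. = FALSE)
  if (any(d < 0)) stop("weights must be non-negative", call. = FALSE)
  if (all(d == 0)) stop("all-zero weights give a zero kinship", call. = FALSE)
  S <- tcrossprod(sweep(Z, 2, d, "*"), Z)
  if (rescale) S <- S * nrow(S) / sum(diag(S))
  kinship_matrix(S, "hem")
}

#' Frequency-weighted IBS genomic kinship
#'
#' \eqn{S = ZZ'/m} on frequency-standardized genotypes; the conventional GRM
#' used for mean-effect trait associations.
#'
#' @param G a [genotype_matrix] (monomorphic SNPs excluded).
#' @return a `kinship_matrix` of kind `"ibs"`.
#' @export
ibs_kinship <- function(G) {
  Z <- standardize(G)$Z
  kinship_matrix(tcrossprod(Z) / ncol(Z), "ibs")
}

#' Build the kinship used by a scan
#'
#' @param G a [genotype_matrix], already MAF-filtered.
#' @param y response vector (required for `method = "hem"`, where the ridge
#'   regression is fitted on it — typically the squared normal scores).
#' @param method `"hem"` or `"ibs"`.
#' @param lambda optional ridge penalty passed to [snp_blup].
#' @return a `kinship_matrix` with accession ids as dimnames.
#' @export
build_kinship <- function(G, y = NULL, method = c("hem", "ibs"), lambda = NULL) {
  method <- match.arg(method)
  S <- if (method == "ibs") {
    ibs_kinship(G)
  } else {
    if (is.null(y)) stop("'y' is required for the HEM kinship", call. = FALSE)
    Zs <- standardize(G)
    fit <- snp_blup(Zs, y, lambda = lambda)
    hem_kinship(Zs, hem_weights(fit))
  }
  dimnames(S) <- list(rownames(G$codes), rownames(G$codes))
  S
}

#' Write / read a kinship matrix as square CSV
#'
#' @param S kinship matrix with accession-id dimnames.
#' @param path CSV path.
#' @return `path` ([write_kinship_csv]) or a `kinship_matrix`
#'   ([read_kinship_csv]).
#' @export
write_kinship_csv <- function(S, path) {
  df <- data.frame(accession_id = rownames(S), as.matrix(S),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship_csv
#' @param kind kinship kind recorded on read (default `"file"`).
#' @export
read_kinship_csv <- function(path, kind = "file") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  kinship_matrix(S, kind)
}
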