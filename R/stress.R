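#' Validate a heat-stress survival count table
#'
#' @param table data frame with columns `experiment`, `genotype`, `survived`,
#'   `total`.
#' @return the table, with factors normalized; errors on invalid counts.
#' @export
stress_table <- function(table) {
  need <- c("experiment", "genotype", "survived", "total")
  if (!all(need %in% names(table)))
    stop("stress table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$survived < 0) || any(table$survived > table$total))
    stop("need 0 <= survived <= total", call. = FALSE)
  if (length(unique(table$genotype)) < 2)
    stop("need >= 2 genotypes", call. = FALSE)
  table
}

#' Log-linear survival regression across replicate experiments
#'
#' Gaussian-family log-link regression of the survivor count on experiment
#' and genotype effects with `log(total)` as offset, so genotype coefficients
#' are log survival-rate ratios: `fold = exp(coef)`. With one experiment and
#' two genotypes the fitted fold equals the raw rate ratio exactly.
#'
#' @param table a [stress_table] data frame.
#' @param reference reference genotype (default: first level).
#' @param family `"gaussian"` (log link, the default) or `"poisson"` for the
#'   more conventional count model; both use the `log(total)` offset.
#' @param epsilon added to zero survivor counts when > 0; with the default 0
#'   a zero cell is an error.
#' @return list with `fold` (named, one per non-reference genotype), `p`
#'   (Wald, asymptotic normal), `coefficients` (full summary table) and the
#'   fitted `model`.
#' @export
survival_loglinear <- function(table, reference = NULL,
                               family = c("gaussian", "poisson"),
                               epsilon = 0) {
  family <- match.arg(family)
  table <- stress_table(table)
  surv <- table$survived
  if (any(surv == 0)) {
    if (epsilon > 0) surv <- surv + epsilon
    else stop("zero survivor cell; set epsilon > 0 to proceed", call. = FALSE)
  }
  geno <- factor(table$genotype)
  if (!is.null(reference)) geno <- stats::relevel(geno, ref = reference)
  expt <- factor(table$experiment)
  df <- data.frame(surv = surv, geno = geno, off = log(table$total))
  form <- if (nlevels(expt) > 1) {
    df$expt <- expt
    surv ~ expt + geno
  } else surv ~ geno
  fam <- if (family == "gaussian") stats::gaussian(link = "log")
         else stats::poisson(link = "log")
  fit <- stats::glm(form, family = fam, data = df, offset = off,
                    mustart = pmax(surv, 0.5))
  cf <- summary(fit)$coefficients
  gi <- grep("^geno", rownames(cf))
  est <- cf[gi, 1]; se <- cf[gi, 2]
  names(est) <- names(se) <- sub("^geno", "", rownames(cf)[gi])
  list(fold = exp(est), p = 2 * stats::pnorm(-abs(est / se)),
       coefficients = cf, model = fit)
}

#' One-sided two-sample t-test
#'
#' Pooled-variance two-sample t-test by default (Welch via `welch = TRUE`),
#' used e.g. for post-stress root growth comparisons.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param alternative `"greater"` (default; tests mean(x) > mean(y)) or
#'   `"less"`.
#' @param welch use the Welch unequal-variance test.
#' @return list with `t`, `df`, `p`.
#' @export
one_sided_t <- function(x, y, alternative = c("greater", "less"),
                        welch = FALSE) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs >= 2 values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both samples", call. = FALSE)
  tt <- stats::t.test(x, y, alternative = alternative, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
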