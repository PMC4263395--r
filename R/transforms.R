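#' Rank-based inverse normal (inverse-Gaussian) transformation
#'
#' Maps a phenotype vector to normal scores
#' \eqn{z_i = \Phi^{-1}\{(r_i - c)/(n - 2c + 1)\}} where \eqn{r_i} is the rank
#' of observation *i* (ties receive average ranks) and *c* is the rank offset,
#' by default Blom's constant 3/8.
#'
#' @param values numeric vector, at least 3 finite values, not all equal.
#' @param c_offset rank-to-quantile offset; default `3/8` (Blom).
#' @return numeric vector of normal scores, same length and order as input.
#' @export
inverse_normal_transform <- function(values, c_offset = 3 / 8) {
  values <- as.numeric(values)
  if (sum(is.finite(values)) < 3)
    stop("need at least 3 finite values", call. = FALSE)
  fin <- is.finite(values)
  v <- values[fin]
  if (diff(range(v)) == 0)
    stop("degenerate input: all values equal", call. = FALSE)
  n <- length(v)
  r <- rank(v, ties.method = "average")
  z <- stats::qnorm((r - c_offset) / (n - 2 * c_offset + 1))
  out <- rep(NA_real_, length(values))
  out[fin] <- z
  names(out) <- names(values)
  out
}

#' Squared normal-score response for variance-heterogeneity scans
#'
#' The phenotype is normalized by the rank-based inverse normal transform and
#' squared: accessions in either tail of the phenotype distribution (broad
#' environmental range for climate variables) get large values of
#' \eqn{y^* = z^2}, so a locus whose minor allele spreads its carriers across
#' the range shifts the mean of \eqn{y^*} for that genotype group.
#'
#' @inheritParams inverse_normal_transform
#' @return object of class `transformed_response`: list with `z` (normal
#'   scores) and `ystar` (`z^2`), both in input order.
#' @export
adaptability_response <- function(values, c_offset = 3 / 8) {
  z <- inverse_normal_transform(values, c_offset)
  structure(list(z = z, ystar = z^2), class = "transformed_response")
}

#' @export
print.transformed_response <- function(x, ...) {
  cat(sprintf("transformed_response: n = %d, mean(ystar) = %.3f\n",
              length(x$z), mean(x$ystar, na.rm = TRUE)))
  invisible(x)
}
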