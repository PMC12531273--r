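#' Minimum sample size for a binary prediction model (Pate-Riley)
#'
#' Computes the minimum number of patients needed to develop a binary-outcome
#' risk prediction model with acceptable shrinkage, following the Pate-Riley
#' criterion
#' \deqn{N = \frac{K}{p(1-p)\, S \, \ln(1-R^2)}}
#' where \eqn{K} is the number of candidate predictors, \eqn{p} the outcome
#' prevalence, \eqn{S} the target shrinkage factor and \eqn{R^2} the
#' anticipated Cox-Snell R-squared. The log term is negative, so the
#' magnitude of the quotient is taken and rounded up.
#'
#' @param k number of candidate predictors (positive).
#' @param p outcome prevalence, strictly between 0 and 1.
#' @param s shrinkage factor, in (0, 1].
#' @param r2 anticipated Cox-Snell R-squared, strictly between 0 and 1.
#' @param val_fraction fraction of the cohort held out for validation,
#'   in (0, 1); the validation size is rounded up.
#' @return a list of class `riley_sample_size` with elements `n_min`,
#'   `n_validation`, `n_training` (integers, `n_validation + n_training ==
#'   n_min`) and the input parameters.
#' @examples
#' riley_min_n(k = 11, p = 0.165, s = 0.9, r2 = 0.05, val_fraction = 0.3)
#' @export
riley_min_n <- function(k, p, s, r2, val_fraction = 0.3) {
  if (!is.numeric(k) || k <= 0) stop_config("k must be a positive number")
  if (p <= 0 || p >= 1) stop_config("prevalence p must lie strictly in (0, 1)")
  if (s <= 0 || s > 1) stop_config("shrinkage s must lie in (0, 1]")
  if (r2 <= 0 || r2 >= 1) {
    stop_config("r2 must lie strictly in (0, 1); r2 = 0 makes the criterion degenerate")
  }
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop_config("val_fraction must lie strictly in (0, 1)")
  }
  n_raw <- k / (p * (1 - p) * s * log(1 - r2))
  n_min <- as.integer(ceiling(abs(n_raw)))
  n_val <- as.integer(ceiling(val_fraction * n_min))
  structure(
    list(n_min = n_min, n_validation = n_val,
         n_training = n_min - n_val, n_raw = abs(n_raw),
         k = k, p = p, s = s, r2 = r2, val_fraction = val_fraction),
    class = "riley_sample_size")
}

#' @export
print.riley_sample_size <- function(x, ...) {
  cat(sprintf(
    "Minimum sample size (K=%g, p=%.3f, S=%.2f, R2=%.3f): %d patients\n",
    x$k, x$p, x$s, x$r2, x$n_min))
  cat(sprintf("  training: %d   validation (%.0f%%): %d\n",
              x$n_training, 100 * x$val_fraction, x$n_validation))
  invisible(x)
}
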