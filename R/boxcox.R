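#' Power-transform specification
#'
#' Describes the monotone normalising transform applied to a raw measure
#' before residualisation: `(x + shift)^lambda`, with `lambda = 0` encoding
#' the natural log. Worked instances from mammographic practice include the
#' cube root of dense areas (`shift = 0, lambda = 1/3`), the fifth root of
#' the brightest areas, and a squared shifted texture score
#' (`shift = -2907, lambda = 2`).
#'
#' @param trait Trait name (may be `NA` for a free-standing spec).
#' @param shift Constant added before powering; the shifted values must be
#'   strictly positive wherever the spec is applied.
#' @param lambda Exponent; 0 means log.
#' @return A one-row tibble of class `transform_spec`.
#' @export
transform_spec <- function(trait = NA_character_, shift = 0, lambda = 1) {
  out <- tibble::tibble(trait = trait, shift = shift, lambda = lambda)
  class(out) <- c("transform_spec", class(out))
  out
}

# Box-Cox profile log-likelihood at lambda (location/scale profiled out).
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  z <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  -n / 2 * log(mean((z - mean(z))^2)) + (lambda - 1) * sum(log(x))
}

#' Fit a Box-Cox power transformation
#'
#' Chooses the exponent maximising the Box-Cox profile log-likelihood of the
#' shifted values over a grid on `[-2, 3]` (step 0.05) followed by
#' golden-section refinement within the bracketing grid interval. The shift
#' is supplied by the caller (default 0 for positive data); it is not
#' estimated.
#'
#' @param values Numeric vector (at least 20 values) with
#'   `values + shift > 0`.
#' @param shift Constant added before powering.
#' @param trait Optional trait name recorded in the returned spec.
#' @param grid Grid of candidate exponents.
#' @return A [transform_spec()].
#' @examples
#' set.seed(1)
#' fit_boxcox(exp(rnorm(500)))$lambda # near 0 (log)
#' @export
fit_boxcox <- function(values, shift = 0, trait = NA_character_,
                       grid = seq(-2, 3, by = 0.05)) {
  if (length(values) < 20) abort("need at least 20 values to fit a transform")
  x <- values + shift
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf(
      "shifted values must be strictly positive (minimum after shift: %.6g)",
      suppressWarnings(min(x, na.rm = TRUE))))
  }
  ll <- vapply(grid, function(l) boxcox_loglik(x, l), numeric(1))
  k <- which.max(ll)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(function(l) boxcox_loglik(x, l), lower = lo, upper = hi,
                  maximum = TRUE, tol = 1e-8)
  lambda <- opt$maximum
  if (abs(lambda) < 1e-4) lambda <- 0
  transform_spec(trait = trait, shift = shift, lambda = lambda)
}

#' Apply a power-transform specification
#'
#' Computes `(values + shift)^lambda` elementwise (`log(values + shift)`
#' when `lambda = 0`). Order-preserving for `lambda > 0`.
#'
#' @param values Numeric vector.
#' @param spec A [transform_spec()] (or anything with `shift` and `lambda`).
#' @return Transformed numeric vector.
#' @examples
#' apply_transform(27, transform_spec(shift = 0, lambda = 1 / 3)) # 3
#' @export
apply_transform <- function(values, spec) {
  x <- values + spec$shift
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf(
      "transform domain violation: minimum shifted value %.6g is not > 0",
      suppressWarnings(min(x, na.rm = TRUE))))
  }
  if (abs(spec$lambda) < 1e-12) log(x) else x^spec$lambda
}
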