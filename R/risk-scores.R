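#' Residualise a trait on covariates and standardise
#'
#' Replaces a trait column by the ordinary least-squares residuals of that
#' column on an intercept plus the named covariates, divided by their sample
#' standard deviation (n - 1 denominator), so the returned column has mean 0
#' and SD 1 exactly. Residuals are computed on individuals, ignoring pair
#' clustering: clustering affects neither the residuals nor their moments,
#' and all inference downstream is cluster-aware.
#'
#' @param data Tibble with the trait and covariate columns; complete cases
#'   required (use the pipeline entry points to drop incomplete pairs).
#' @param trait Column to residualise.
#' @param covariates Character vector of covariate column names.
#' @return `data` with the trait column replaced by its standardised
#'   residual.
#' @export
residualize_standardize <- function(data, trait, covariates = "age") {
  v <- adjustment_fit(data, trait, covariates)
  r <- resid(v$fit)
  data[[trait]] <- as.vector(r / sd(r))
  data
}

adjustment_fit <- function(data, trait, covariates) {
  missing_cols <- setdiff(c(trait, covariates), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  X <- data[, covariates, drop = FALSE]
  const <- vapply(X, function(col) var(as.numeric(col)) < 1e-24, logical(1))
  if (any(const)) {
    abort(paste0("constant covariate(s): ",
                 paste(covariates[const], collapse = ", ")))
  }
  if (anyNA(data[, c(trait, covariates)])) {
    abort("missing values present; analyses use complete pairs only")
  }
  fm <- stats::as.formula(paste0(
    "`", trait, "` ~ ", paste0("`", covariates, "`", collapse = " + ")))
  fit <- lm(fm, data = data)
  alias <- is.na(coef(fit))
  if (any(alias)) {
    abort(paste0("collinear covariate(s): ",
                 paste(names(coef(fit))[alias], collapse = ", ")))
  }
  list(fit = fit, r_squared = summary(fit)$r.squared)
}

#' Fraction of trait variance explained by the adjustment covariates
#'
#' R-squared of the ordinary regression of the (already transformed) trait
#' column on the covariates; with age alone this is the share of variance
#' explained by age at mammography.
#'
#' @inheritParams residualize_standardize
#' @return A number in `[0, 1]`.
#' @export
variance_explained <- function(data, trait, covariates = "age") {
  adjustment_fit(data, trait, covariates)$r_squared
}

#' Build mammogram-style risk scores from raw twin-pair measures
#'
#' Implements the score-construction pipeline: each raw measure is carried
#' to an approximately normal scale by a Box-Cox power transformation
#' (fitted by profile likelihood, or forced via `transforms`), adjusted for
#' the covariates (age at mammography by default) by ordinary least squares,
#' and the residuals standardised to mean 0, SD 1. Incomplete pairs are
#' dropped first with a reported count.
#'
#' @param data Twin-pair tibble (`pair_id`, `twin_index`, covariates, raw
#'   trait columns), e.g. from [simulate_pairs()] or [read_pairs()].
#' @param traits Character vector of trait columns to score.
#' @param covariates Covariates to adjust for (default `"age"`).
#' @param transforms Optional named list of [transform_spec()]s forcing the
#'   normalising transform per trait (e.g.
#'   [mammographic_transform_specs()]); `"identity"` skips transformation;
#'   `NULL` fits Box-Cox per trait.
#' @param shifts Optional named numeric vector of Box-Cox shifts per trait
#'   used when fitting (default 0).
#' @return A tibble (`pair_id`, `twin_index`, one standardised score column
#'   per trait) of class `falcon_scores`, with attributes `transforms`
#'   (specs used) and `r_squared` (adjustment R-squared per trait).
#' @examples
#' cfg <- calibrate_pair_config("light_areas", "bright_areas",
#'   rho_x = 0.59, rho_y = 0.53, r_within = 0.81, r_cross = 0.52,
#'   n_pairs = 200, raw_transforms = mammographic_transforms()[1:2]
#' )
#' scores <- risk_scores(simulate_pairs(cfg),
#'                       c("light_areas", "bright_areas"))
#' colMeans(scores[c("light_areas", "bright_areas")]) # ~0
#' @export
risk_scores <- function(data, traits, covariates = "age",
                        transforms = NULL, shifts = NULL) {
  data <- complete_pairs(data, c(traits, covariates))
  identity_all <- identical(transforms, "identity")
  specs <- list()
  r2 <- numeric(0)
  out <- data[, c("pair_id", "twin_index", covariates), drop = FALSE]
  for (tr in traits) {
    spec <- if (identity_all) {
      NULL
    } else if (!is.null(transforms[[tr]])) {
      transforms[[tr]]
    } else if (is.null(transforms)) {
      fit_boxcox(data[[tr]], shift = shifts[[tr]] %||% 0, trait = tr)
    } else {
      NULL
    }
    v <- if (is.null(spec)) data[[tr]] else apply_transform(data[[tr]], spec)
    tmp <- data
    tmp[[tr]] <- v
    r2[tr] <- variance_explained(tmp, tr, covariates)
    out[[tr]] <- residualize_standardize(tmp, tr, covariates)[[tr]]
    specs[[tr]] <- spec %||% transform_spec(tr, 0, 1)
  }
  out <- out[, c("pair_id", "twin_index", traits)]
  attr(out, "transforms") <- specs
  attr(out, "r_squared") <- r2
  attr(out, "covariates") <- covariates
  class(out) <- c("falcon_scores", class(out))
  out
}

#' Adjust risk scores for a third risk score
#'
#' Residualises the predictor and outcome scores on a third score and
#' re-standardises them. Because every score is already an age-adjusted OLS
#' residual, residualising on the (equally age-adjusted) third score is
#' exactly equivalent, by the Frisch-Waugh-Lovell theorem, to adjusting the
#' transformed measures for age and the third score jointly.
#'
#' @param scores A [risk_scores()] tibble.
#' @param traits Score columns to adjust.
#' @param third The adjusting score column.
#' @return The scores tibble with the named columns re-residualised.
#' @export
adjust_for_third_score <- function(scores, traits, third) {
  for (tr in traits) {
    scores <- residualize_standardize(scores, tr, covariates = third)
  }
  scores
}
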