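fisher_ci <- function(r, n_units, conf_level = 0.95) {
  if (n_units <= 3) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  hw <- qnorm(1 - (1 - conf_level) / 2) / sqrt(n_units - 3)
  tanh(c(z - hw, z + hw))
}

check_pair_layout <- function(scores) {
  counts <- table(scores$pair_id)
  bad <- names(counts)[counts != 2]
  if (length(bad) > 0) {
    abort(paste0("pair(s) without exactly two twins: ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  dplyr::arrange(scores, .data$pair_id, .data$twin_index)
}

twin_columns <- function(scores, trait) {
  s <- check_pair_layout(scores)
  v <- s[[trait]]
  if (is.null(v)) abort(paste0("no such score column: ", trait))
  list(t1 = v[s$twin_index == 1], t2 = v[s$twin_index == 2])
}

correlation_entry <- function(kind, trait_x, trait_y, a, b, n_units,
                              conf_level = 0.95) {
  if (var(a) < 1e-24 || var(b) < 1e-24) {
    abort(paste0("zero variance in correlation inputs for ",
                 trait_x, " / ", trait_y))
  }
  r <- cor(a, b)
  ci <- fisher_ci(r, n_units, conf_level)
  tibble::tibble(kind = kind, trait_x = trait_x, trait_y = trait_y,
                 r = r, ci_low = ci[1], ci_high = ci[2],
                 n_units = as.integer(n_units))
}

#' Within-pair correlation of a risk score
#'
#' Pearson correlation of a trait between the two members of each pair,
#' computed on double-entered tuples: each pair contributes `(v1, v2)` and
#' `(v2, v1)`, the standard twin-study convention, which makes the estimate
#' invariant to twin labelling. The Fisher-z confidence interval uses the
#' number of pairs by default, avoiding the anti-conservative intervals that
#' duplicated tuples would give; `n_convention = "double"` uses 2 x pairs.
#'
#' @param scores A [risk_scores()] tibble (or any tibble with `pair_id`,
#'   `twin_index` and the score column).
#' @param trait Score column name.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @param n_convention `"pairs"` (default) or `"double"`: the effective n
#'   used for the interval.
#' @return One-row tibble: `kind`, `trait_x`, `trait_y`, `r`, `ci_low`,
#'   `ci_high`, `n_units`.
#' @export
within_pair_correlation <- function(scores, trait, conf_level = 0.95,
                                    n_convention = c("pairs", "double")) {
  n_convention <- match.arg(n_convention)
  tc <- twin_columns(scores, trait)
  n <- length(tc$t1) * switch(n_convention, pairs = 1L, double = 2L)
  correlation_entry("within_twin_within_trait", trait, trait,
                    c(tc$t1, tc$t2), c(tc$t2, tc$t1), n, conf_level)
}

#' Cross-trait correlations of two risk scores
#'
#' The within-twin cross-trait correlation (a person's `x` with her own `y`;
#' one tuple per individual) and the cross-twin cross-trait correlation (a
#' person's `x` with her co-twin's `y`, double-entered; interval on the
#' number of pairs by default).
#'
#' @inheritParams within_pair_correlation
#' @param trait_x,trait_y Score column names.
#' @return Two-row tibble of correlation entries.
#' @export
cross_trait_correlations <- function(scores, trait_x, trait_y,
                                     conf_level = 0.95,
                                     n_convention = c("pairs", "double")) {
  n_convention <- match.arg(n_convention)
  x <- twin_columns(scores, trait_x)
  y <- twin_columns(scores, trait_y)
  n_pairs <- length(x$t1)
  within <- correlation_entry(
    "within_twin_cross_trait", trait_x, trait_y,
    c(x$t1, x$t2), c(y$t1, y$t2), 2L * n_pairs, conf_level)
  n_cross <- n_pairs * switch(n_convention, pairs = 1L, double = 2L)
  cross <- correlation_entry(
    "cross_twin_cross_trait", trait_x, trait_y,
    c(x$t1, x$t2), c(y$t2, y$t1), n_cross, conf_level)
  dplyr::bind_rows(within, cross)
}

#' Full twin-pair correlation table
#'
#' Assembles the correlation structure of a set of risk scores: the
#' within-pair correlation of every trait and, for every unordered trait
#' pair, the within-twin and cross-twin cross-trait correlations.
#'
#' @inheritParams within_pair_correlation
#' @param traits Score columns to include.
#' @return A tibble of correlation entries of class `falcon_correlations`.
#' @examples
#' cfg <- calibrate_pair_config("x", "y", 0.59, 0.53, 0.81, 0.52,
#'                              n_pairs = 371)
#' sc <- risk_scores(simulate_pairs(cfg), c("x", "y"),
#'                   transforms = "identity")
#' twin_correlations(sc, c("x", "y"))
#' @export
twin_correlations <- function(scores, traits, conf_level = 0.95,
                              n_convention = c("pairs", "double")) {
  n_convention <- match.arg(n_convention)
  rows <- purrr::map(traits, function(tr) {
    within_pair_correlation(scores, tr, conf_level, n_convention)
  })
  if (length(traits) > 1) {
    combs <- utils::combn(traits, 2, simplify = FALSE)
    rows <- c(rows, purrr::map(combs, function(pp) {
      cross_trait_correlations(scores, pp[1], pp[2], conf_level,
                               n_convention)
    }))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("falcon_correlations", class(out))
  out
}

#' Write a correlation table as TSV
#'
#' @param correlations A [twin_correlations()] tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(correlations, path) {
  utils::write.table(correlations, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
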