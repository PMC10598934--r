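#' @export
print.falcon_analysis <- function(x, ...) {
  cat("ICE FALCON analysis: ", x$predictor, " <-> ", x$outcome,
      if (!is.null(x$adjust_for)) paste0(" (adjusted for ", x$adjust_for, ")"),
      "\n", sep = "")
  cat("  pairs: ", x$n_pairs, ", bootstrap B = ", x$B,
      ", alpha = ", x$alpha, "\n", sep = "")
  for (nm in c("forward", "reverse")) {
    d <- x[[nm]]
    dec <- d$decomposition
    lab <- x$conclusions$label[x$conclusions$direction == nm]
    cat(sprintf(
      "  %s (%s -> %s): beta_self %.3f -> %.3f, beta_cotwin %.3f -> %.3f, rho %.2f\n",
      nm, d$predictor, d$outcome, dec$beta_self, dec$beta_self_prime,
      dec$beta_cotwin, dec$beta_cotwin_prime, dec$rho))
    cat(sprintf("    label: %s", lab))
    if (lab %in% c("causation", "combination")) {
      cat(sprintf(" | Pr = %.0f%%, causal effect = %.3f, confounding = %.0f%%",
                  100 * dec$pr, dec$causal_effect,
                  100 * dec$confounding_fraction))
    }
    cat("\n")
  }
  cat("  summary:", x$summary, "\n")
  invisible(x)
}

#' @exportS3Method
tidy.falcon_triplet <- function(x, ...) {
  tibble::tibble(
    model = x$model, role = x$role, term = x$term,
    estimate = x$estimate, std.error = x$std_error, p.value = x$p_value
  )
}

#' @exportS3Method
tidy.falcon_analysis <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$forward$triplet), direction = "forward",
                  predictor = x$forward$predictor,
                  outcome = x$forward$outcome, .before = 1),
    dplyr::mutate(tidy(x$reverse$triplet), direction = "reverse",
                  predictor = x$reverse$predictor,
                  outcome = x$reverse$outcome, .before = 1)
  )
}

#' @exportS3Method
glance.falcon_analysis <- function(x, ...) {
  cl <- x$conclusions
  tibble::tibble(
    predictor = x$predictor,
    outcome = x$outcome,
    adjust_for = x$adjust_for %||% NA_character_,
    n_pairs = x$n_pairs,
    label_forward = cl$label[cl$direction == "forward"],
    label_reverse = cl$label[cl$direction == "reverse"],
    pr_forward = cl$pr[cl$direction == "forward"],
    pr_reverse = cl$pr[cl$direction == "reverse"],
    summary = x$summary,
    B = x$B,
    alpha = x$alpha
  )
}

#' Formatted, rounded analysis table
#'
#' Renders one bidirectional analysis as the conventional reporting layout:
#' one row per direction and role with the Model 1/2 coefficient, the
#' Model 3 coefficient, the change and its bootstrap p-value, and (on self
#' rows of causal directions) the causal fraction and conclusion.
#' Rounding rules: coefficients and standard errors to 3 decimals, `rho`
#' to 2, `Pr` and the confounding fraction to integer percent; every value
#' is the stored full-precision value rounded by exactly these rules.
#'
#' @param analysis A [run_pair_analysis()] result.
#' @return A tibble.
#' @export
format_falcon_table <- function(analysis) {
  rows <- purrr::map(c("forward", "reverse"), function(nm) {
    d <- analysis[[nm]]
    dec <- d$decomposition
    lab <- analysis$conclusions$label[analysis$conclusions$direction == nm]
    causal <- lab %in% c("causation", "combination")
    tv <- d$triplet
    get <- function(term, col) tv[[col]][tv$term == term]
    concl <- if (causal) {
      sprintf("%s causes %s (%.0f%%)", d$predictor, d$outcome, 100 * dec$pr)
    } else {
      sprintf("not consistent with %s causing %s", d$predictor, d$outcome)
    }
    tibble::tibble(
      assignment = paste0(d$predictor, "-", d$outcome),
      role = c("self", "cotwin"),
      coef_unconditional = round(c(get("beta_self", "estimate"),
                                   get("beta_cotwin", "estimate")), 3),
      se_unconditional = round(c(get("beta_self", "std_error"),
                                 get("beta_cotwin", "std_error")), 3),
      p_unconditional = c(get("beta_self", "p_value"),
                          get("beta_cotwin", "p_value")),
      coef_conditional = round(c(get("beta_self_prime", "estimate"),
                                 get("beta_cotwin_prime", "estimate")), 3),
      se_conditional = round(c(get("beta_self_prime", "std_error"),
                               get("beta_cotwin_prime", "std_error")), 3),
      p_conditional = c(get("beta_self_prime", "p_value"),
                        get("beta_cotwin_prime", "p_value")),
      change = round(c(dec$change_self, dec$change_cotwin), 3),
      change_p = c(dec$change_p_self, dec$change_p_cotwin),
      rho = round(dec$rho, 2),
      pr_pct = if (causal) round(100 * dec$pr) else NA_real_,
      causal_effect = if (causal) round(dec$causal_effect, 3) else NA_real_,
      confounding_pct = if (causal) {
        round(100 * dec$confounding_fraction)
      } else NA_real_,
      conclusion = concl
    )
  })
  dplyr::bind_rows(rows)
}

#' Coefficient plot for an ICE FALCON analysis
#'
#' Dot-and-interval plot of the four coefficients (with 95% robust
#' intervals) for each direction: a causal signature shows the co-twin
#' coefficient collapsing towards zero between the unconditional and
#' conditional models while the self coefficient is stable.
#'
#' @param object A `falcon_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.falcon_analysis <- function(object, ...) {
  td <- tidy(object)
  td$which <- ifelse(td$model == 3, "conditional (Model 3)",
                     "unconditional (Models 1-2)")
  td$dir_label <- paste0(td$predictor, " → ", td$outcome)
  ggplot2::ggplot(
    td,
    ggplot2::aes(x = .data$role, y = .data$estimate,
                 colour = .data$which, group = .data$which)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std.error,
                   ymax = .data$estimate + 1.96 * .data$std.error),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::facet_wrap(~dir_label) +
    ggplot2::labs(x = "predictor role", y = "GEE coefficient",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Correlation-structure plot
#'
#' Point-and-interval display of a [twin_correlations()] table by
#' correlation kind.
#'
#' @param object A `falcon_correlations` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.falcon_correlations <- function(object, ...) {
  object$pair <- ifelse(object$trait_x == object$trait_y, object$trait_x,
                        paste(object$trait_x, object$trait_y, sep = " / "))
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$pair, y = .data$r)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~kind, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Pearson correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
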