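#' The four ICE FALCON regression coefficients
#'
#' Container for the coefficients of the three-model procedure: the
#' unconditional self coefficient (Model 1: a twin's outcome on her own
#' predictor), the unconditional co-twin coefficient (Model 2: her outcome
#' on her co-twin's predictor), and the two conditional coefficients of
#' Model 3 (both predictors jointly).
#'
#' @param beta_self,beta_cotwin,beta_self_prime,beta_cotwin_prime Point
#'   estimates.
#' @param se Optional named numeric of robust standard errors (same four
#'   names).
#' @param p Optional named numeric of two-sided p-values.
#' @return A tibble of class `falcon_triplet` with one row per coefficient:
#'   `model`, `role`, `term`, `estimate`, `std_error`, `p_value`.
#' @export
falcon_triplet <- function(beta_self, beta_cotwin, beta_self_prime,
                           beta_cotwin_prime, se = NULL, p = NULL) {
  terms <- c("beta_self", "beta_cotwin", "beta_self_prime",
             "beta_cotwin_prime")
  est <- c(beta_self, beta_cotwin, beta_self_prime, beta_cotwin_prime)
  if (any(!is.finite(est))) abort("all four coefficients must be finite")
  out <- tibble::tibble(
    model = c(1L, 2L, 3L, 3L),
    role = c("self", "cotwin", "self", "cotwin"),
    term = terms,
    estimate = est,
    std_error = if (is.null(se)) NA_real_ else unname(se[terms]),
    p_value = if (is.null(p)) NA_real_ else unname(p[terms])
  )
  class(out) <- c("falcon_triplet", class(out))
  out
}

triplet_values <- function(triplet) {
  if (inherits(triplet, "falcon_triplet")) {
    setNames(triplet$estimate, triplet$term)
  } else if (is.list(triplet) || is.data.frame(triplet)) {
    need <- c("beta_self", "beta_cotwin", "beta_self_prime",
              "beta_cotwin_prime")
    miss <- setdiff(need, names(triplet))
    if (length(miss) > 0) {
      abort(paste0("triplet missing: ", paste(miss, collapse = ", ")))
    }
    vapply(need, function(nm) as.numeric(triplet[[nm]][1]), numeric(1))
  } else {
    abort("triplet must be a falcon_triplet, list or data frame")
  }
}

#' Fit the three ICE FALCON models
#'
#' Fits Models 1-3 by Gaussian GEE (cluster = twin pair, robust sandwich
#' SEs; see [fit_gee()] for the working-correlation choice) on the
#' double-entered design for one predictor-outcome assignment, and
#' assembles the coefficient triplet.
#'
#' @param scores A [risk_scores()] tibble.
#' @param predictor,outcome Score column names.
#' @param conditional If `TRUE`, additionally conditions every model on the
#'   co-twin's outcome value as a covariate (a stricter reading of
#'   "conditioning on the co-twin's outcome"); the default accounts for the
#'   outcome correlation through the working correlation instead.
#' @param corstr Working correlation passed to [fit_gee()].
#' @return A [falcon_triplet()] with robust SEs and p-values; attributes
#'   `fits` (the three `falcon_gee` objects) and `n_pairs`.
#' @export
fit_models <- function(scores, predictor, outcome, conditional = FALSE,
                       corstr = "independence") {
  design <- build_double_entry(scores, predictor, outcome)
  extra <- if (conditional) "y_cotwin" else character(0)
  m1 <- fit_gee(design, c("x_self", extra), corstr = corstr)
  m2 <- fit_gee(design, c("x_cotwin", extra), corstr = corstr)
  m3 <- fit_gee(design, c("x_self", "x_cotwin", extra), corstr = corstr)
  se <- c(beta_self = m1$robust_se[["x_self"]],
          beta_cotwin = m2$robust_se[["x_cotwin"]],
          beta_self_prime = m3$robust_se[["x_self"]],
          beta_cotwin_prime = m3$robust_se[["x_cotwin"]])
  p <- c(beta_self = m1$p_values[["x_self"]],
         beta_cotwin = m2$p_values[["x_cotwin"]],
         beta_self_prime = m3$p_values[["x_self"]],
         beta_cotwin_prime = m3$p_values[["x_cotwin"]])
  out <- falcon_triplet(
    m1$coefficients[["x_self"]],
    m2$coefficients[["x_cotwin"]],
    m3$coefficients[["x_self"]],
    m3$coefficients[["x_cotwin"]],
    se = se, p = p
  )
  attr(out, "fits") <- list(model1 = m1, model2 = m2, model3 = m3)
  attr(out, "n_pairs") <- m1$n_clusters
  attr(out, "predictor") <- predictor
  attr(out, "outcome") <- outcome
  out
}

# Fast triplet point estimates for bootstrap replicates: the independence
# point estimates (double-entered least squares, matching fit_models'
# default weighting) via closed-form moment solves; no sandwich needed.
triplet_coefs_fast <- function(y, xs, xc) {
  n <- length(y)
  my <- mean(y)
  ms <- mean(xs)
  mc <- mean(xc)
  yc <- y - my
  sc_ <- xs - ms
  cc <- xc - mc
  vss <- sum(sc_^2)
  vcc <- sum(cc^2)
  vsc <- sum(sc_ * cc)
  cys <- sum(yc * sc_)
  cyc <- sum(yc * cc)
  b1 <- cys / vss
  b2 <- cyc / vcc
  det <- vss * vcc - vsc^2
  b3s <- (cys * vcc - cyc * vsc) / det
  b3c <- (cyc * vss - cys * vsc) / det
  c(beta_self = b1, beta_cotwin = b2,
    beta_self_prime = b3s, beta_cotwin_prime = b3c)
}

#' Cluster-bootstrap tests for the Model 1 to Model 3 coefficient changes
#'
#' Resamples twin pairs with replacement, refits Models 1-3 on each
#' replicate, and forms the two change statistics
#' `beta_self - beta_self_prime` and `beta_cotwin - beta_cotwin_prime`.
#' Two-sided p-values use the normal approximation with the bootstrap
#' standard error. Replicates whose resampled predictor is degenerate are
#' dropped and counted; more than 5% dropped is an error.
#'
#' @inheritParams fit_models
#' @param B Number of bootstrap replicates (>= 200 for reporting; default
#'   1000).
#' @param seed Integer seed; the same seed and `B` always reproduce the
#'   same p-values.
#' @return One-row tibble: `change_self`, `change_cotwin` (observed),
#'   `boot_se_self`, `boot_se_cotwin`, `change_p_self`, `change_p_cotwin`,
#'   `B`, `n_dropped`.
#' @export
bootstrap_changes <- function(scores, predictor, outcome, B = 1000,
                              seed = NULL, conditional = FALSE) {
  if (B < 200) warn("B < 200 is below the recommended minimum for reporting")
  if (!is.null(seed)) set.seed(seed)
  design <- build_double_entry(scores, predictor, outcome)
  y <- design$y_self
  xs <- design$x_self
  xc <- design$x_cotwin
  n_pairs <- nrow(design) / 2
  obs <- triplet_coefs_fast(y, xs, xc)
  changes <- matrix(NA_real_, B, 2)
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n_pairs, n_pairs, replace = TRUE)
    rows <- rbind(2 * idx - 1, 2 * idx)
    dim(rows) <- NULL
    xb <- xs[rows]
    if (var(xb) < 1e-12 || var(y[rows]) < 1e-12) {
      dropped <- dropped + 1L
      next
    }
    cf <- triplet_coefs_fast(y[rows], xb, xc[rows])
    changes[b, ] <- c(cf["beta_self"] - cf["beta_self_prime"],
                      cf["beta_cotwin"] - cf["beta_cotwin_prime"])
  }
  if (dropped > 0.05 * B) {
    abort(sprintf("%d of %d bootstrap replicates degenerate", dropped, B))
  }
  keep <- stats::complete.cases(changes)
  se <- apply(changes[keep, , drop = FALSE], 2, sd)
  d_obs <- c(obs["beta_self"] - obs["beta_self_prime"],
             obs["beta_cotwin"] - obs["beta_cotwin_prime"])
  p <- 2 * pnorm(-abs(d_obs) / se)
  tibble::tibble(
    change_self = unname(d_obs[1]),
    change_cotwin = unname(d_obs[2]),
    boot_se_self = se[1],
    boot_se_cotwin = se[2],
    change_p_self = unname(p[1]),
    change_p_cotwin = unname(p[2]),
    B = as.integer(B),
    n_dropped = dropped
  )
}

#' Decompose a pairwise association into causal and confounded fractions
#'
#' Applies the path-tracing decomposition to the three-model coefficients:
#' with change-in-self `beta_self - beta_self_prime`, change-in-co-twin
#' `beta_cotwin - beta_cotwin_prime`, and `rho` the within-pair correlation
#' of the predictor,
#' `pr = ((change_cotwin - (change_self / beta_self) * beta_cotwin) / rho) /
#' beta_self` is the fraction of the Model 1 association attributable to
#' causation, `beta_self * pr` is the causal effect size, and `1 - pr` the
#' familial-confounding fraction. A `pr` outside `[0, 1]` is returned as-is
#' with `pr_out_of_range = TRUE`, never clamped.
#'
#' @param triplet A [falcon_triplet()], or any list/one-row data frame with
#'   `beta_self`, `beta_cotwin`, `beta_self_prime`, `beta_cotwin_prime`.
#' @param rho Within-pair correlation of the predictor risk score (from
#'   [within_pair_correlation()]); must be nonzero.
#' @param change_p_self,change_p_cotwin Optional p-values for the two
#'   coefficient changes (from [bootstrap_changes()]), carried along for
#'   [infer_conclusion()].
#' @return One-row tibble: coefficients, changes, `rho`, `pr`,
#'   `causal_effect`, `confounding_fraction`, `pr_out_of_range`, change
#'   p-values.
#' @examples
#' decompose(
#'   falcon_triplet(0.802, 0.513, 0.770, 0.070),
#'   rho = 0.59
#' )$pr # ~0.893
#' @export
decompose <- function(triplet, rho, change_p_self = NA_real_,
                      change_p_cotwin = NA_real_) {
  v <- triplet_values(triplet)
  if (!is.finite(rho) || abs(rho) < 1e-12) {
    abort("rho must be nonzero: the decomposition divides by the ",
          "within-pair predictor correlation")
  }
  if (abs(v[["beta_self"]]) < 1e-12) {
    abort("beta_self must be nonzero: the decomposition divides by it")
  }
  change_self <- v[["beta_self"]] - v[["beta_self_prime"]]
  change_cotwin <- v[["beta_cotwin"]] - v[["beta_cotwin_prime"]]
  pr <- ((change_cotwin - (change_self / v[["beta_self"]]) *
            v[["beta_cotwin"]]) / rho) / v[["beta_self"]]
  tibble::tibble(
    beta_self = v[["beta_self"]],
    beta_cotwin = v[["beta_cotwin"]],
    beta_self_prime = v[["beta_self_prime"]],
    beta_cotwin_prime = v[["beta_cotwin_prime"]],
    change_self = change_self,
    change_cotwin = change_cotwin,
    rho = rho,
    pr = pr,
    causal_effect = v[["beta_self"]] * pr,
    confounding_fraction = 1 - pr,
    pr_out_of_range = pr < 0 || pr > 1,
    change_p_self = change_p_self,
    change_p_cotwin = change_p_cotwin
  )
}

# Decision rules for one predictor->outcome direction.
label_direction <- function(decomposition, p_beta_cotwin, alpha = 0.05,
                            similar_tol = 0.25) {
  d <- decomposition
  if (is.na(p_beta_cotwin) || p_beta_cotwin >= alpha) return("no_evidence")
  cotwin_sig <- !is.na(d$change_p_cotwin) && d$change_p_cotwin < alpha
  self_sig <- !is.na(d$change_p_self) && d$change_p_self < alpha
  toward_zero <- abs(d$beta_cotwin_prime) < abs(d$beta_cotwin)
  if (!(cotwin_sig && toward_zero)) return("inconsistent")
  if (!self_sig) return("causation")
  prop_self <- d$change_self / d$beta_self
  prop_cotwin <- d$change_cotwin / d$beta_cotwin
  if (abs(prop_self - prop_cotwin) < similar_tol) return("familial_confounding")
  if (prop_self < prop_cotwin) return("combination")
  "inconsistent"
}

#' Reconcile the two directions of an ICE FALCON analysis
#'
#' Labels each direction by the pattern of its coefficients and coefficient
#' changes, then reconciles: causation requires a nonzero co-twin
#' coefficient whose conditional version moves towards zero while the self
#' coefficient is stable; familial confounding requires both coefficients to
#' attenuate significantly to a similar proportional extent; a combination
#' shows both, with the self coefficient changing proportionally less.
#' Directions whose coefficients move away from zero, or change without the
#' causal signature, are labelled inconsistent (not consistent with the
#' predictor causing the outcome). The causal fraction is reported only from
#' directions labelled causation or combination.
#'
#' @param forward,reverse Lists with elements `triplet` (a
#'   [falcon_triplet()] with p-values) and `decomposition` (a [decompose()]
#'   row carrying change p-values), for the two assignments of predictor
#'   and outcome.
#' @param alpha Nominal significance level (default 0.05).
#' @param similar_tol Tolerance on the difference of proportional changes
#'   used by the familial-confounding rule.
#' @return A tibble with one row per direction: `direction`, `label`, `pr`
#'   (NA unless the direction is causal), `causal_effect`,
#'   `confounding_fraction`, plus a `summary` attribute with the reconciled
#'   verdict.
#' @export
infer_conclusion <- function(forward, reverse, alpha = 0.05,
                             similar_tol = 0.25) {
  one <- function(dir, nm) {
    p_bc <- triplet_p(dir$triplet, "beta_cotwin")
    lab <- label_direction(dir$decomposition, p_bc, alpha, similar_tol)
    causal <- lab %in% c("causation", "combination")
    tibble::tibble(
      direction = nm,
      label = lab,
      pr = if (causal) dir$decomposition$pr else NA_real_,
      causal_effect = if (causal) dir$decomposition$causal_effect else NA_real_,
      confounding_fraction = if (causal) {
        dir$decomposition$confounding_fraction
      } else NA_real_
    )
  }
  out <- dplyr::bind_rows(one(forward, "forward"), one(reverse, "reverse"))
  causal_dirs <- out$direction[out$label %in% c("causation", "combination")]
  attr(out, "summary") <- if (length(causal_dirs) == 2) {
    "bidirectional causation (with familial confounding where Pr < 1)"
  } else if (length(causal_dirs) == 1) {
    paste0("one-directional causation (", causal_dirs, ")")
  } else if (all(out$label == "no_evidence")) {
    "no evidence of association"
  } else {
    "no direction consistent with causation"
  }
  out
}

triplet_p <- function(triplet, term) {
  if (inherits(triplet, "falcon_triplet")) {
    triplet$p_value[triplet$term == term]
  } else {
    as.numeric(triplet[[paste0("p_", term)]] %||% NA_real_)
  }
}

#' Run a full bidirectional ICE FALCON analysis for one trait pair
#'
#' End-to-end analysis of one predictor-outcome assignment and its reverse:
#' optional third-score adjustment of both scores (with the within-pair
#' predictor correlation recomputed on the adjusted score), three-model GEE
#' fits, cluster-bootstrap change tests, path-tracing decomposition, and
#' decision labels for both directions.
#'
#' @inheritParams fit_models
#' @param adjust_for Optional third score column; both analysis scores are
#'   residualised on it first (blocking pathways through that score).
#' @param B,seed Bootstrap control; see [bootstrap_changes()].
#' @param alpha,similar_tol Decision-rule parameters; see
#'   [infer_conclusion()].
#' @return A `falcon_analysis` object: per-direction triplets, bootstrap
#'   results, decompositions and labels, plus the reconciled conclusion.
#'   Supports [tidy()], [glance()], [autoplot()] and
#'   [format_falcon_table()].
#' @export
run_pair_analysis <- function(scores, predictor, outcome, adjust_for = NULL,
                              B = 1000, seed = NULL, alpha = 0.05,
                              similar_tol = 0.25, conditional = FALSE) {
  if (predictor == outcome) abort("predictor and outcome must differ")
  if (!is.null(adjust_for) && adjust_for %in% c(predictor, outcome)) {
    abort("adjust_for must differ from predictor and outcome")
  }
  if (!is.null(adjust_for)) {
    scores <- adjust_for_third_score(scores, c(predictor, outcome),
                                     adjust_for)
  }
  seed <- seed %||% 1L
  run_direction <- function(pred, out, dir_seed) {
    triplet <- fit_models(scores, pred, out, conditional = conditional)
    boot <- bootstrap_changes(scores, pred, out, B = B, seed = dir_seed,
                              conditional = conditional)
    rho <- within_pair_correlation(scores, pred)$r
    dec <- decompose(triplet, rho,
                     change_p_self = boot$change_p_self,
                     change_p_cotwin = boot$change_p_cotwin)
    list(predictor = pred, outcome = out, triplet = triplet,
         bootstrap = boot, rho = rho, decomposition = dec)
  }
  fwd <- run_direction(predictor, outcome, seed)
  rev <- run_direction(outcome, predictor, seed + 1L)
  conclusions <- infer_conclusion(fwd, rev, alpha = alpha,
                                  similar_tol = similar_tol)
  structure(
    list(
      predictor = predictor, outcome = outcome, adjust_for = adjust_for,
      forward = fwd, reverse = rev, conclusions = conclusions,
      summary = attr(conclusions, "summary"),
      alpha = alpha, similar_tol = similar_tol, B = as.integer(B),
      seed = seed, n_pairs = attr(fwd$triplet, "n_pairs")
    ),
    class = "falcon_analysis"
  )
}

#' Median-split stratified ICE FALCON analysis
#'
#' Partitions complete pairs into two subgroups at a cutpoint of a
#' pair-level stratifier (the within-pair mean of the stratifier column;
#' median cutpoint by default, so a continuous stratifier over an even
#' number of pairs gives two equal groups), rebuilds risk scores within
#' each subgroup, and runs the full bidirectional analysis per subgroup.
#'
#' @param data Raw twin-pair tibble (see [simulate_pairs()]).
#' @param predictor,outcome Raw trait columns to analyse.
#' @param stratifier Stratifier column name (default `"stratifier"`).
#' @param cutpoint Pair-level cutpoint; default the median of the pair
#'   means.
#' @param covariates,transforms Passed to [risk_scores()].
#' @param ... Passed to [run_pair_analysis()].
#' @return A list with `cutpoint` and one `falcon_analysis` per stratum
#'   (`low` = at or below the cutpoint, `high` = above), each carrying an
#'   `n_pairs` element.
#' @export
stratified_analysis <- function(data, predictor, outcome,
                                stratifier = "stratifier", cutpoint = NULL,
                                covariates = "age", transforms = NULL, ...) {
  if (!stratifier %in% names(data)) {
    abort(paste0("no stratifier column: ", stratifier))
  }
  data <- complete_pairs(data, c(predictor, outcome, covariates, stratifier))
  pair_level <- dplyr::summarise(
    dplyr::group_by(data, .data$pair_id),
    strat = mean(.data[[stratifier]]), .groups = "drop")
  if (var(pair_level$strat) < 1e-24) abort("stratifier is constant")
  cutpoint <- cutpoint %||% median(pair_level$strat)
  groups <- list(
    low = pair_level$pair_id[pair_level$strat <= cutpoint],
    high = pair_level$pair_id[pair_level$strat > cutpoint]
  )
  res <- purrr::imap(groups, function(ids, nm) {
    n <- length(ids)
    if (n < 5) {
      abort(sprintf("stratum '%s' has only %d pairs (< 5)", nm, n))
    }
    if (n < 30) {
      warn(sprintf("stratum '%s' has only %d pairs (< 30)", nm, n))
    }
    sub <- data[data$pair_id %in% ids, , drop = FALSE]
    sc <- risk_scores(sub, c(predictor, outcome), covariates = covariates,
                      transforms = transforms)
    out <- run_pair_analysis(sc, predictor, outcome, ...)
    out$n_pairs <- n
    out
  })
  c(list(cutpoint = cutpoint, stratifier = stratifier), res)
}
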