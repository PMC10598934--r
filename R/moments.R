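#' Exact population moments of a simulated trait pair
#'
#' Computes, in closed form, the covariance matrix of
#' `(x_self, x_cotwin, y_self, y_cotwin)` implied by a [sim_config()] on the
#' standardised latent scale (the scale of the risk scores after age
#' adjustment and standardisation, since age is independent of the latent
#' components and is removed exactly by the population regression). With
#' reduced form `M = (I - B)^-1`, shared shock covariance
#' `S = diag(familial^2) + L L'` and unique covariance `E = diag(unique^2)`,
#' the within-person trait covariance is `M (S + E) M'` and the cross-twin
#' covariance is `M S M'`.
#'
#' Optionally the moments can be partialled on a third trait: each
#' individual's `x` and `y` are residualised on that individual's own third
#' score, matching the third-score adjustment of the estimation pipeline.
#'
#' @param config A [sim_config()].
#' @param predictor,outcome Trait names for the analysis pair.
#' @param adjust_for Optional third trait to partial out.
#' @return A `falcon_moments` object: list with `cov` (4 x 4 matrix, unit
#'   diagonal blocks), `rho_x` (within-pair predictor correlation), and the
#'   trait names.
#' @export
population_moments <- function(config, predictor, outcome,
                               adjust_for = NULL) {
  stopifnot(inherits(config, "sim_config"))
  traits <- config$traits
  for (tr in c(predictor, outcome, adjust_for)) {
    if (!tr %in% traits) abort(paste0("trait not in config: ", tr))
  }
  p <- length(traits)
  B <- path_matrix(config)
  M <- solve(diag(p) - B)
  L <- confounder_matrix(config)
  S <- diag(config$familial_loading^2, p) +
    (if (ncol(L) > 0) L %*% t(L) else 0)
  E <- diag(config$unique_sd^2, p)
  W <- M %*% (S + E) %*% t(M) # within-person
  X <- M %*% S %*% t(M)       # cross-twin
  dimnames(W) <- dimnames(X) <- list(traits, traits)

  i <- predictor
  j <- outcome
  use <- c(i, j, adjust_for)
  # full covariance over (t_self, t_cotwin) for the used traits
  m <- length(use)
  full <- matrix(0, 2 * m, 2 * m)
  nm <- c(paste0(use, "_self"), paste0(use, "_cotwin"))
  dimnames(full) <- list(nm, nm)
  full[seq_len(m), seq_len(m)] <- W[use, use]
  full[m + seq_len(m), m + seq_len(m)] <- W[use, use]
  full[seq_len(m), m + seq_len(m)] <- X[use, use]
  full[m + seq_len(m), seq_len(m)] <- t(X[use, use])

  if (!is.null(adjust_for)) {
    # residualise each individual's x and y on her own third score
    z <- adjust_for
    vz <- W[z, z]
    a_x <- W[i, z] / vz
    a_y <- W[j, z] / vz
    tf <- diag(2 * m)
    rownames(tf) <- colnames(tf) <- nm
    tf[paste0(i, "_self"), paste0(z, "_self")] <- -a_x
    tf[paste0(j, "_self"), paste0(z, "_self")] <- -a_y
    tf[paste0(i, "_cotwin"), paste0(z, "_cotwin")] <- -a_x
    tf[paste0(j, "_cotwin"), paste0(z, "_cotwin")] <- -a_y
    full <- tf %*% full %*% t(tf)
  }

  keep <- c(paste0(i, "_self"), paste0(i, "_cotwin"),
            paste0(j, "_self"), paste0(j, "_cotwin"))
  cv <- full[keep, keep]
  sds <- sqrt(diag(cv))
  cv <- cv / tcrossprod(sds)
  dimnames(cv) <- list(c("x_self", "x_cotwin", "y_self", "y_cotwin"),
                       c("x_self", "x_cotwin", "y_self", "y_cotwin"))
  structure(
    list(cov = cv, rho_x = cv["x_self", "x_cotwin"],
         predictor = predictor, outcome = outcome, adjust_for = adjust_for),
    class = "falcon_moments"
  )
}

#' @export
print.falcon_moments <- function(x, ...) {
  cat("<falcon_moments> predictor:", x$predictor, " outcome:", x$outcome,
      if (!is.null(x$adjust_for)) paste0(" (adjusted for ", x$adjust_for, ")"),
      "\n")
  print(round(x$cov, 4))
  invisible(x)
}

#' Exact population values of the three-model coefficients and decomposition
#'
#' Evaluates, without simulation, what the ICE FALCON procedure estimates
#' under a given structural configuration: the Model 1 and Model 2
#' coefficients as covariance ratios, the Model 3 coefficients by solving
#' the 2 x 2 normal equations, and the full causal decomposition from those
#' exact values. This is the oracle against which the estimation pipeline is
#' validated.
#'
#' @inheritParams population_moments
#' @return A list with `moments` ([population_moments()] result), `triplet`
#'   (an exact [falcon_triplet()]), and `decomposition` (a [decompose()]
#'   row).
#' @examples
#' cfg <- sim_config(100, c("x", "y"), paths = c("x->y" = 0.4),
#'                   familial_loading = c(x = 0.6, y = 0),
#'                   unique_sd = c(x = 0.8, y = 0.8))
#' theoretical_coefficients(cfg, "x", "y")$decomposition$pr # exactly 1
#' @export
theoretical_coefficients <- function(config, predictor, outcome,
                                     adjust_for = NULL) {
  mom <- population_moments(config, predictor, outcome,
                            adjust_for = adjust_for)
  cv <- mom$cov
  rho <- mom$rho_x
  if (abs(abs(rho) - 1) < 1e-12) {
    abort("|rho_x| = 1: the Model 3 normal equations are singular")
  }
  beta_self <- cv["y_self", "x_self"]
  beta_cotwin <- cv["y_self", "x_cotwin"]
  b3 <- solve(matrix(c(1, rho, rho, 1), 2),
              c(beta_self, beta_cotwin))
  triplet <- falcon_triplet(
    beta_self = beta_self, beta_cotwin = beta_cotwin,
    beta_self_prime = b3[1], beta_cotwin_prime = b3[2]
  )
  dec <- tryCatch(decompose(triplet, rho = rho), error = function(e) NULL)
  list(
    moments = mom,
    triplet = triplet,
    decomposition = dec
  )
}

#' Configure a simulation with a chosen population causal fraction
#'
#' Builds a two-trait configuration (`x` predictor, `y` outcome) whose exact
#' population decomposition has `pr` equal to a requested causal fraction
#' `f`. The predictor keeps a within-pair correlation of `rho_x`; for
#' `f = 0` the causal path is absent and the association is purely
#' familially confounded, for `f = 1` the confounder does not load on the
#' outcome, and intermediate fractions are reached by solving for the
#' outcome-side confounder loading with [uniroot()] on the closed-form
#' decomposition.
#'
#' @param f Target causal fraction in `[0, 1]`.
#' @param n_pairs,seed Passed to [sim_config()].
#' @param rho_x Within-pair correlation of the predictor.
#' @param path Causal path coefficient used when `f > 0`.
#' @return A `sim_config` with attribute `"true_pr"` holding the achieved
#'   exact population `pr`.
#' @export
sim_config_causal_fraction <- function(f, n_pairs = 1000, seed = 1L,
                                       rho_x = 0.5, path = 0.3) {
  stopifnot(f >= 0, f <= 1)
  build <- function(b, cy, ey = 0.8) {
    cx <- sqrt(rho_x / 2)
    sim_config(
      n_pairs = n_pairs, traits = c("x", "y"),
      paths = if (b != 0) c("x->y" = b) else NULL,
      familial_loading = c(x = cx, y = 0.3),
      unique_sd = c(x = sqrt(1 - rho_x), y = ey),
      confounders = list(shared = c(x = cx, y = cy)),
      seed = seed
    )
  }
  pr_of <- function(b, cy) {
    theoretical_coefficients(build(b, cy), "x", "y")$decomposition$pr
  }
  if (f == 0) {
    # purely confounded member: a strong confounder loading and small
    # outcome noise keep the marginal association comparable to the causal
    # members, so the estimated fraction has similar precision across the
    # whole truth grid
    cfg <- build(0, 1.5, ey = 0.4)
  } else if (f == 1) {
    cfg <- build(path, 0)
  } else {
    root <- uniroot(function(cy) pr_of(path, cy) - f,
                    lower = 1e-6, upper = 5, tol = 1e-10)
    cfg <- build(path, root$root)
  }
  attr(cfg, "true_pr") <-
    theoretical_coefficients(cfg, "x", "y")$decomposition$pr
  cfg
}
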