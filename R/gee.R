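#' Build the double-entered regression design for a trait pair
#'
#' Expands standardised scores into the paired regression layout: each twin
#' appears once as "self", with her own predictor, her co-twin's predictor,
#' and her co-twin's outcome attached, in both orderings (two rows per
#' pair). Rows are ordered by `(pair_id, twin_index)`, so relabelling twins
#' within pairs maps the design onto itself.
#'
#' @param scores A [risk_scores()] tibble.
#' @param predictor,outcome Score column names.
#' @return Tibble with columns `cluster`, `twin_index`, `y_self`, `x_self`,
#'   `x_cotwin`, `y_cotwin`.
#' @export
build_double_entry <- function(scores, predictor, outcome) {
  s <- check_pair_layout(scores)
  if (anyNA(s[, c(predictor, outcome)])) {
    bad <- unique(s$pair_id[!complete.cases(s[, c(predictor, outcome)])])
    abort(paste0("incomplete pair(s): ", paste(head(bad, 10), collapse = ", ")))
  }
  x <- s[[predictor]]
  y <- s[[outcome]]
  n <- nrow(s)
  swap <- ifelse(seq_len(n) %% 2 == 1, seq_len(n) + 1, seq_len(n) - 1)
  tibble::tibble(
    cluster = s$pair_id,
    twin_index = s$twin_index,
    y_self = y,
    x_self = x,
    x_cotwin = x[swap],
    y_cotwin = y[swap]
  )
}

# Core Gaussian GEE solver on a design matrix with clusters of size 2 whose
# rows are adjacent. Exchangeable working correlation is re-estimated by
# moments each iteration; robust (sandwich) covariance at convergence.
gee_engine <- function(X, y, corstr = "exchangeable", maxit = 50,
                       tol = 1e-10) {
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    abort("singular regression design (collinear terms)")
  }
  i1 <- seq(1, n, by = 2)
  i2 <- seq(2, n, by = 2)
  swap <- function(m) {
    if (is.matrix(m)) {
      out <- m
      out[i1, ] <- m[i2, ]
      out[i2, ] <- m[i1, ]
    } else {
      out <- m
      out[i1] <- m[i2]
      out[i2] <- m[i1]
    }
    out
  }
  beta <- qr.coef(qrX, y)
  alpha <- 0
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  for (it in seq_len(maxit)) {
    iter <- it
    r <- as.vector(y - X %*% beta)
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable") {
      alpha <- if (phi < 1e-300) 0 else mean(r[i1] * r[i2]) / phi
      alpha <- max(min(alpha, 0.999), -0.999)
    }
    Xs <- swap(X)
    ys <- swap(y)
    A <- crossprod(X, X - alpha * Xs)
    beta_new <- tryCatch(solve(A, crossprod(X, y - alpha * ys)),
                         error = function(e) abort(
                           "singular GEE estimating equations"))
    delta <- max(abs(beta_new - beta))
    trace <- c(trace, delta)
    beta <- as.vector(beta_new)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(paste0(
      "GEE did not converge in ", maxit, " iterations; max coefficient ",
      "updates per iteration: ",
      paste(sprintf("%.2e", utils::tail(trace, 5)), collapse = ", ")))
  }
  r <- as.vector(y - X %*% beta)
  phi <- sum(r^2) / (n - p)
  # residual within-pair correlation: the exchangeable moment estimate,
  # reported as a diagnostic whatever weighting was used
  alpha_resid <- if (phi < 1e-300) 0 else mean(r[i1] * r[i2]) / phi
  Xs <- swap(X)
  bread <- solve(crossprod(X, X - alpha * Xs))
  g <- X * (r - alpha * swap(r)) # row contributions to X' R^-1 r
  G <- rowsum(g, rep(seq_len(n / 2), each = 2))
  vcov <- bread %*% crossprod(G) %*% bread
  list(beta = beta, vcov = vcov, alpha = alpha, alpha_resid = alpha_resid,
       phi = phi, iterations = iter, converged = converged)
}

#' Fit a Gaussian GEE on a double-entered twin design
#'
#' Marginal linear regression of `y_self` on the requested terms with an
#' intercept, estimated by generalised estimating equations clustering on
#' twin pair with robust sandwich standard errors. The default
#' `corstr = "independence"` gives point estimates identical to ordinary
#' least squares on the double-entered rows while the sandwich accounts for
#' the pairing; this is the only weighting that estimates the marginal
#' (unconditional) coefficients in Models 1 and 2, because those mean models
#' deliberately omit the other cluster member's covariates, and any
#' non-diagonal working correlation then mixes the omitted within-cluster
#' covariances into the estimating equations. `corstr = "exchangeable"`
#' (moment estimator iterated with the coefficients) is available and is
#' consistent for mean models that include all cluster covariates, such as
#' Model 3.
#'
#' @param design A [build_double_entry()] tibble.
#' @param terms Non-empty subset of `c("x_self", "x_cotwin", "y_cotwin")`
#'   (`y_cotwin` gives the conditional variant that regresses on the
#'   co-twin's outcome rather than accounting for it through the cluster
#'   structure).
#' @param corstr Working correlation: `"independence"` (default) or
#'   `"exchangeable"`.
#' @param maxit,tol Iteration control.
#' @return A `falcon_gee` object with `coefficients`, `robust_se`,
#'   `p_values` (two-sided normal), `working_correlation` (the exchangeable
#'   moment estimate of the residual within-pair correlation, reported as a
#'   diagnostic whatever weighting was used), `n_clusters`.
#' @export
fit_gee <- function(design, terms = c("x_self", "x_cotwin"),
                    corstr = c("independence", "exchangeable"),
                    maxit = 50, tol = 1e-10) {
  corstr <- match.arg(corstr)
  if (length(terms) == 0) abort("terms must be non-empty")
  bad <- setdiff(terms, c("x_self", "x_cotwin", "y_cotwin"))
  if (length(bad) > 0) {
    abort(paste0("unknown term(s): ", paste(bad, collapse = ", ")))
  }
  n_clusters <- length(unique(design$cluster))
  if (n_clusters < 30) {
    warn(sprintf("only %d clusters; robust standard errors may be unstable",
                 n_clusters))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(design[, terms, drop = FALSE]))
  fit <- gee_engine(X, design$y_self, corstr = corstr, maxit = maxit,
                    tol = tol)
  se <- sqrt(pmax(diag(fit$vcov), 0))
  z <- ifelse(se > 0, fit$beta / se, Inf * sign(fit$beta))
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  structure(
    list(
      coefficients = setNames(fit$beta, colnames(X)),
      robust_se = setNames(se, colnames(X)),
      p_values = setNames(p, colnames(X)),
      vcov = fit$vcov,
      working_correlation = fit$alpha_resid,
      dispersion = fit$phi,
      corstr = corstr,
      n_clusters = n_clusters,
      iterations = fit$iterations,
      terms = terms
    ),
    class = "falcon_gee"
  )
}

#' @export
print.falcon_gee <- function(x, ...) {
  cat("Gaussian GEE (", x$corstr, " working correlation, ",
      x$n_clusters, " twin-pair clusters)\n", sep = "")
  print(tidy(x))
  cat("working correlation:", sprintf("%.4f", x$working_correlation),
      " dispersion:", sprintf("%.4f", x$dispersion), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.falcon_gee <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$robust_se),
    statistic = unname(x$coefficients / x$robust_se),
    p.value = unname(x$p_values)
  )
}

#' @exportS3Method
glance.falcon_gee <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters,
    working_correlation = x$working_correlation,
    dispersion = x$dispersion,
    corstr = x$corstr,
    iterations = x$iterations
  )
}
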