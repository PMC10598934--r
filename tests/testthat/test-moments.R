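# independent oracle: build the 4-variable covariance by stacking the full
# linear map from every exogenous shock (pair-shared factors, confounders,
# and each twin's unique shocks) to the observed traits of both twins
brute_force_cov <- function(config, predictor, outcome) {
  traits <- config$traits
  p <- length(traits)
  B <- matrix(0, p, p, dimnames = list(traits, traits))
  for (nm in names(config$paths)) {
    pr <- strsplit(nm, "->", fixed = TRUE)[[1]]
    B[pr[2], pr[1]] <- config$paths[[nm]]
  }
  M <- solve(diag(p) - B)
  k <- length(config$confounders)
  L <- matrix(0, p, k, dimnames = list(traits, NULL))
  for (j in seq_len(k)) {
    lo <- config$confounders[[j]]
    L[names(lo), j] <- lo
  }
  A1 <- cbind(M %*% diag(config$familial_loading, p),
              if (k > 0) M %*% L else NULL,
              M %*% diag(config$unique_sd, p),
              matrix(0, p, p))
  A2 <- cbind(M %*% diag(config$familial_loading, p),
              if (k > 0) M %*% L else NULL,
              matrix(0, p, p),
              M %*% diag(config$unique_sd, p))
  W <- A1 %*% t(A1)
  X <- A1 %*% t(A2)
  dimnames(W) <- dimnames(X) <- list(traits, traits)
  i <- predictor
  j <- outcome
  cv <- rbind(
    c(W[i, i], X[i, i], W[i, j], X[i, j]),
    c(X[i, i], W[i, i], X[j, i], W[i, j]),
    c(W[i, j], X[j, i], W[j, j], X[j, j]),
    c(X[i, j], W[i, j], X[j, j], W[j, j])
  )
  sds <- sqrt(diag(cv))
  cv / tcrossprod(sds)
}

test_that("closed-form moments agree with the brute-force linear-map oracle", {
  set.seed(71)
  for (rep in 1:10) {
    cfg <- sim_config(
      10, c("x", "y", "z"),
      paths = c("x->y" = runif(1, -0.5, 0.5), "y->x" = runif(1, -0.4, 0.4),
                "z->y" = runif(1, -0.4, 0.4)),
      familial_loading = c(x = runif(1, 0, 0.8), y = runif(1, 0, 0.8),
                           z = runif(1, 0, 0.8)),
      unique_sd = c(x = runif(1, 0.3, 1), y = runif(1, 0.3, 1),
                    z = runif(1, 0.3, 1)),
      confounders = list(c1 = c(x = runif(1, -0.6, 0.6),
                                y = runif(1, -0.6, 0.6),
                                z = runif(1, -0.6, 0.6)))
    )
    m <- population_moments(cfg, "x", "y")
    expect_equal(unname(m$cov), unname(brute_force_cov(cfg, "x", "y")),
                 tolerance = 1e-12)
  }
})

test_that("moments are exchangeable and rho_x is the cross-twin entry", {
  cfg <- config_confounded()
  m <- population_moments(cfg, "x", "y")
  swap <- c(2, 1, 4, 3) # exchange self/co-twin labels for both traits
  expect_equal(unname(m$cov), unname(m$cov[swap, swap]), tolerance = 1e-12)
  expect_identical(m$rho_x, m$cov["x_self", "x_cotwin"])
  ev <- eigen(m$cov, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("pure causation gives beta_cotwin = rho * beta_self and Pr = 1", {
  cfg <- config_causal(b = 0.4)
  th <- theoretical_coefficients(cfg, "x", "y")
  v <- setNames(th$triplet$estimate, th$triplet$term)
  rho <- th$moments$rho_x
  expect_equal(v[["beta_cotwin"]], rho * v[["beta_self"]],
               tolerance = 1e-12)
  expect_equal(v[["beta_cotwin_prime"]], 0, tolerance = 1e-12)
  expect_equal(v[["beta_self_prime"]], v[["beta_self"]], tolerance = 1e-12)
  expect_equal(th$decomposition$pr, 1, tolerance = 1e-12)
})

test_that("pure familial confounding gives equal coefficients and Pr = 0", {
  cfg <- config_confounded()
  th <- theoretical_coefficients(cfg, "x", "y")
  v <- setNames(th$triplet$estimate, th$triplet$term)
  expect_equal(v[["beta_self"]], v[["beta_cotwin"]], tolerance = 1e-12)
  expect_equal(v[["beta_self_prime"]], v[["beta_cotwin_prime"]],
               tolerance = 1e-12)
  expect_equal(th$decomposition$pr, 0, tolerance = 1e-12)
})

test_that("mixed configurations match direct numeric inversion", {
  cfg <- sim_config(
    10, c("x", "y"),
    paths = c("x->y" = 0.3),
    familial_loading = c(x = 0.5, y = 0.3),
    unique_sd = c(x = 0.7, y = 0.8),
    confounders = list(shared = c(x = 0.5, y = 0.4))
  )
  cv <- brute_force_cov(cfg, "x", "y")
  rho <- cv[1, 2]
  bs <- cv[3, 1]
  bc <- cv[3, 2]
  b3 <- solve(cv[1:2, 1:2], cv[3, 1:2])
  th <- theoretical_coefficients(cfg, "x", "y")
  expect_equal(th$triplet$estimate, c(bs, bc, b3[1], b3[2]),
               tolerance = 1e-12)
})

test_that("third-score partialling blocks a mediated pathway", {
  # x -> z -> y chain only: adjusting for z should kill the x-y association
  cfg <- sim_config(
    10, c("x", "z", "y"),
    paths = c("x->z" = 0.5, "z->y" = 0.5),
    familial_loading = c(x = 0.5, z = 0.2, y = 0.2),
    unique_sd = c(x = 0.8, z = 0.7, y = 0.8)
  )
  un <- theoretical_coefficients(cfg, "x", "y")
  expect_gt(un$triplet$estimate[1], 0.1)
  ad <- theoretical_coefficients(cfg, "x", "y", adjust_for = "z")
  expect_equal(ad$triplet$estimate[1], 0, tolerance = 1e-12)
  expect_null(ad$decomposition) # degenerate: no association left to split
})

test_that("singular Model 3 systems are rejected", {
  cfg <- sim_config(10, c("x", "y"),
                    familial_loading = c(x = 1, y = 0.3),
                    unique_sd = c(x = 1e-9, y = 0.8),
                    confounders = list(shared = c(x = 0, y = 0.4)))
  expect_error(theoretical_coefficients(cfg, "x", "y"), "singular")
})

test_that("causal-fraction configs achieve their target Pr exactly", {
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    cfg <- sim_config_causal_fraction(f, n_pairs = 10)
    expect_equal(attr(cfg, "true_pr"), f, tolerance = 1e-8)
  }
})

test_that("calibrated pair configs reproduce their correlation targets", {
  cfg <- calibrate_pair_config("a", "b", rho_x = 0.34, rho_y = 0.48,
                               r_within = 0.43, r_cross = 0.28)
  m <- population_moments(cfg, "a", "b")
  expect_equal(m$cov["x_self", "x_cotwin"], 0.34, tolerance = 1e-10)
  expect_equal(m$cov["y_self", "y_cotwin"], 0.48, tolerance = 1e-10)
  expect_equal(m$cov["x_self", "y_self"], 0.43, tolerance = 1e-10)
  expect_equal(m$cov["x_self", "y_cotwin"], 0.28, tolerance = 1e-10)
  expect_error(
    calibrate_pair_config("a", "b", 0.1, 0.1, 0.9, 0.1),
    "infeasible"
  )
})
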