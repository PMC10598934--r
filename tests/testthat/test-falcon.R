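test_that("fit_models shows the causal signature under pure causation", {
  cfg <- config_causal(n_pairs = 20000, b = 0.4)
  sc <- latent_scores(cfg, seed = 2)
  tr <- fit_models(sc, "x", "y")
  v <- setNames(tr$estimate, tr$term)
  se <- setNames(tr$std_error, tr$term)
  expect_lt(abs(v["beta_cotwin_prime"]), 3 * se["beta_cotwin_prime"])
  expect_lt(abs(v["beta_self_prime"] - v["beta_self"]),
            3 * se["beta_self_prime"])
  expect_gt(v["beta_cotwin"] / se["beta_cotwin"], 5)
})

test_that("fit_models shows symmetric attenuation under pure confounding", {
  cfg <- config_confounded(n_pairs = 20000)
  sc <- latent_scores(cfg, seed = 3)
  tr <- fit_models(sc, "x", "y")
  v <- setNames(tr$estimate, tr$term)
  expect_equal(v[["beta_self"]], v[["beta_cotwin"]], tolerance = 0.05)
  expect_equal(v[["beta_self_prime"]], v[["beta_cotwin_prime"]],
               tolerance = 0.05)
  expect_lt(v[["beta_self_prime"]], v[["beta_self"]])
})

test_that("independent traits give four null coefficients", {
  cfg <- config_independent(n_pairs = 20000)
  sc <- latent_scores(cfg, seed = 4)
  tr <- fit_models(sc, "x", "y")
  expect_lt(max(abs(tr$estimate)), 4 * max(tr$std_error))
})

test_that("decomposition reproduces reported causal fractions", {
  d1 <- decompose(falcon_triplet(0.802, 0.513, 0.770, 0.070), rho = 0.59)
  expect_equal(round(100 * d1$pr), 89)
  expect_equal(round(d1$causal_effect, 1), 0.7)
  d2 <- decompose(falcon_triplet(0.680, 0.378, 0.653, 0.058), rho = 0.53)
  expect_equal(round(100 * d2$pr), 85)
})

test_that("decomposition identities hold", {
  # pure causation: beta_cotwin = rho * b collapses to zero conditionally
  for (b in c(0.2, 0.5, -0.4)) {
    for (rho in c(0.3, 0.59)) {
      d <- decompose(falcon_triplet(b, rho * b, b, 0), rho = rho)
      expect_equal(d$pr, 1, tolerance = 1e-12)
    }
  }
  # equal coefficients with equal changes: numerator cancels identically
  d <- decompose(falcon_triplet(0.5, 0.5, 0.38, 0.38), rho = 0.44)
  expect_equal(d$pr, 0, tolerance = 1e-12)
  # bookkeeping invariants
  d <- decompose(falcon_triplet(0.6, 0.3, 0.55, 0.1), rho = 0.5)
  expect_identical(d$change_self, d$beta_self - d$beta_self_prime)
  expect_lt(abs(d$causal_effect + d$beta_self * d$confounding_fraction -
                  d$beta_self), 1e-12)
})

test_that("pr is invariant to rescaling predictor or outcome", {
  set.seed(51)
  for (i in 1:50) {
    v <- rnorm(4, sd = 0.5)
    v[1] <- v[1] + sign(v[1]) * 0.2 # keep beta_self away from 0
    rho <- runif(1, 0.2, 0.8)
    base <- decompose(falcon_triplet(v[1], v[2], v[3], v[4]), rho = rho)$pr
    ky <- runif(1, 0.1, 10) # rescale outcome: all betas scale together
    sy <- decompose(falcon_triplet(ky * v[1], ky * v[2], ky * v[3],
                                   ky * v[4]), rho = rho)$pr
    expect_equal(sy, base, tolerance = 1e-10)
    kx <- runif(1, 0.1, 10) # rescale predictor: betas scale by 1/kx
    sx <- decompose(falcon_triplet(v[1] / kx, v[2] / kx, v[3] / kx,
                                   v[4] / kx), rho = rho)$pr
    expect_equal(sx, base, tolerance = 1e-10)
  }
})

test_that("out-of-range pr is flagged, never clamped", {
  d <- decompose(falcon_triplet(0.3, 0.25, 0.35, 0.02), rho = 0.4)
  expect_gt(d$pr, 1)
  expect_true(d$pr_out_of_range)
  expect_error(decompose(falcon_triplet(0.5, 0.2, 0.4, 0.1), rho = 0),
               "rho")
  expect_error(decompose(falcon_triplet(0, 0.2, 0, 0.1), rho = 0.5),
               "beta_self")
})

test_that("bootstrap p-values are seeded and reproducible", {
  cfg <- config_confounded(n_pairs = 150)
  sc <- latent_scores(cfg, seed = 5)
  b1 <- bootstrap_changes(sc, "x", "y", B = 250, seed = 42)
  b2 <- bootstrap_changes(sc, "x", "y", B = 250, seed = 42)
  expect_identical(b1, b2)
  b3 <- bootstrap_changes(sc, "x", "y", B = 250, seed = 43)
  expect_false(identical(b1$change_p_self, b3$change_p_self))
  expect_warning(bootstrap_changes(sc, "x", "y", B = 100, seed = 1),
                 "B < 200")
})

test_that("pure confounding yields similar, significant changes", {
  cfg <- config_confounded(n_pairs = 2000)
  sc <- latent_scores(cfg, seed = 6)
  b <- bootstrap_changes(sc, "x", "y", B = 400, seed = 7)
  expect_lt(b$change_p_self, 0.01)
  expect_lt(b$change_p_cotwin, 0.01)
  expect_equal(b$change_self, b$change_cotwin, tolerance = 0.25)
})

test_that("conclusion labels follow the decision rules", {
  mk <- function(bs, bc, bsp, bcp, rho, p_bc, cps, cpc) {
    tr <- falcon_triplet(bs, bc, bsp, bcp,
                         p = c(beta_self = 1e-10, beta_cotwin = p_bc,
                               beta_self_prime = 1e-8,
                               beta_cotwin_prime = 0.5))
    list(triplet = tr,
         decomposition = decompose(tr, rho, change_p_self = cps,
                                   change_p_cotwin = cpc))
  }
  # textbook causation: co-twin collapses, self stable
  fwd <- mk(0.60, 0.30, 0.58, 0.02, 0.5, 1e-8, 0.4, 1e-6)
  # reverse: coefficients move away from zero
  rev <- mk(0.45, 0.20, 0.50, 0.28, 0.4, 1e-4, 0.01, 0.01)
  out <- infer_conclusion(fwd, rev)
  expect_equal(out$label, c("causation", "inconsistent"))
  expect_equal(attr(out, "summary"), "one-directional causation (forward)")
  expect_true(is.na(out$pr[2]))
  # both directions causal
  out2 <- infer_conclusion(fwd, mk(0.6, 0.3, 0.57, 0.03, 0.5, 1e-6, 0.3,
                                   1e-5))
  expect_match(attr(out2, "summary"), "bidirectional")
  # proportionally similar significant attenuation: familial confounding
  conf <- mk(0.50, 0.48, 0.30, 0.29, 0.55, 1e-6, 1e-4, 1e-4)
  expect_equal(infer_conclusion(conf, conf)$label[1],
               "familial_confounding")
  # combination: both changes significant, self proportionally smaller
  comb <- mk(0.80, 0.51, 0.77, 0.07, 0.59, 1e-8, 0.02, 1e-8)
  expect_equal(infer_conclusion(comb, comb)$label[1], "combination")
  # null association
  null <- mk(0.02, 0.01, 0.02, 0.01, 0.5, 0.8, 0.9, 0.9)
  out3 <- infer_conclusion(null, null)
  expect_equal(out3$label, c("no_evidence", "no_evidence"))
  expect_equal(attr(out3, "summary"), "no evidence of association")
})

test_that("run_pair_analysis recovers structure end to end", {
  cfg <- config_causal(n_pairs = 3000, b = 0.5)
  sc <- latent_scores(cfg, seed = 8)
  an <- run_pair_analysis(sc, "x", "y", B = 300, seed = 9)
  expect_s3_class(an, "falcon_analysis")
  cl <- an$conclusions
  expect_equal(cl$label[cl$direction == "forward"], "causation")
  expect_equal(cl$pr[cl$direction == "forward"], 1, tolerance = 0.15)
  gl <- glance(an)
  expect_equal(gl$predictor, "x")
  td <- tidy(an)
  expect_equal(nrow(td), 8)
  expect_error(run_pair_analysis(sc, "x", "x"), "differ")
  expect_error(run_pair_analysis(sc, "x", "y", adjust_for = "x"),
               "adjust_for")
})

test_that("adjusting for an irrelevant third score is a near no-op", {
  cfg <- sim_config(
    4000, c("x", "y", "z"),
    paths = c("x->y" = 0.4),
    familial_loading = c(x = 0.6, y = 0.2, z = 0.6),
    unique_sd = c(x = 0.8, y = 0.8, z = 0.8))
  sc <- latent_scores(cfg, seed = 10)
  plain <- run_pair_analysis(sc, "x", "y", B = 200, seed = 11)
  adj <- run_pair_analysis(sc, "x", "y", adjust_for = "z", B = 200,
                           seed = 11)
  expect_equal(adj$forward$decomposition$pr, plain$forward$decomposition$pr,
               tolerance = 0.1)
  expect_equal(adj$forward$rho, plain$forward$rho, tolerance = 0.05)
})

test_that("adjusting for a mediator blocks the causal pathway", {
  cfg <- sim_config(
    20000, c("x", "z", "y"),
    paths = c("x->z" = 0.5, "z->y" = 0.5),
    familial_loading = c(x = 0.5, z = 0.2, y = 0.2),
    unique_sd = c(x = 0.8, z = 0.7, y = 0.8))
  sc <- latent_scores(cfg, seed = 12)
  tr_plain <- fit_models(sc, "x", "y")
  expect_gt(tr_plain$estimate[1], 0.15)
  adj <- adjust_for_third_score(sc, c("x", "y"), "z")
  tr_adj <- fit_models(adj, "x", "y")
  expect_lt(abs(tr_adj$estimate[1]), 0.02)
})

test_that("stratified analysis splits pairs at the median and runs", {
  cfg <- calibrate_pair_config(
    "x", "y", 0.5, 0.5, 0.7, 0.4, n_pairs = 200, seed = 1,
    stratifier = list(loadings = list(x = 0.7), noise_sd = 0.5,
                      mean = 30.5, scale = 8))
  d <- simulate_pairs(cfg, seed = 13)
  res <- stratified_analysis(d, "x", "y", transforms = "identity",
                             B = 200, seed = 14)
  expect_equal(res$low$n_pairs, 100)
  expect_equal(res$high$n_pairs, 100)
  expect_s3_class(res$low, "falcon_analysis")
  d$flat <- 1
  expect_error(stratified_analysis(d, "x", "y", stratifier = "flat"),
               "constant")
  expect_error(stratified_analysis(d, "x", "y", stratifier = "none"),
               "no stratifier")
})
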