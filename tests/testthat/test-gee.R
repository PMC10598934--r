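test_that("double entry expands a small fixture exactly", {
  sc <- four_pair_scores()
  de <- build_double_entry(sc, "x", "y")
  expect_equal(nrow(de), 8)
  expect_equal(de$cluster, rep(1:4, each = 2))
  expect_equal(de$x_self, sc$x)
  expect_equal(de$x_cotwin, c(2, 1, 1, 2, 4, 3, 3, 4))
  expect_equal(de$y_self, sc$y)
  expect_equal(de$y_cotwin, c(1, 2, 2, 1, 3, 4, 4, 3))
})

test_that("double entry is invariant to twin relabelling up to row order", {
  cfg <- config_confounded(n_pairs = 60)
  sc <- latent_scores(cfg, seed = 2)
  de <- build_double_entry(sc, "x", "y")
  flipped <- sc
  flipped$twin_index <- 3L - flipped$twin_index
  de2 <- build_double_entry(
    dplyr::arrange(flipped, pair_id, twin_index), "x", "y")
  key <- function(d) d[order(d$cluster, d$y_self, d$x_self), ]
  expect_equal(key(de)$x_cotwin, key(de2)$x_cotwin)
  expect_equal(key(de)$y_cotwin, key(de2)$y_cotwin)
})

test_that("incomplete pairs are rejected with their ids", {
  sc <- four_pair_scores()[-1, ]
  expect_error(build_double_entry(sc, "x", "y"), "1")
  sc2 <- four_pair_scores()
  sc2$x[3] <- NA
  expect_error(build_double_entry(sc2, "x", "y"), "incomplete pair.*2")
})

test_that("a deterministic outcome gives coefficient 1 and zero residual", {
  cfg <- config_confounded(n_pairs = 100)
  sc <- latent_scores(cfg, seed = 3)
  sc$y <- sc$x
  fit <- fit_gee(build_double_entry(sc, "x", "y"), "x_self")
  expect_equal(unname(fit$coefficients["x_self"]), 1, tolerance = 1e-10)
  expect_lt(fit$dispersion, 1e-16)
})

test_that("independence weighting reproduces least squares exactly", {
  cfg <- config_confounded(n_pairs = 150)
  sc <- latent_scores(cfg, seed = 4)
  de <- build_double_entry(sc, "x", "y")
  fit <- fit_gee(de, c("x_self", "x_cotwin"), corstr = "independence")
  ols <- lm(y_self ~ x_self + x_cotwin, data = de)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
})

test_that("robust errors match the cluster sandwich of an OLS fit", {
  skip_if_not_installed("sandwich")
  cfg <- config_confounded(n_pairs = 200)
  sc <- latent_scores(cfg, seed = 5)
  de <- build_double_entry(sc, "x", "y")
  fit <- fit_gee(de, c("x_self", "x_cotwin"), corstr = "independence")
  ols <- lm(y_self ~ x_self + x_cotwin, data = de)
  vc <- sandwich::vcovCL(ols, cluster = de$cluster, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(fit$robust_se), unname(sqrt(diag(vc))),
               tolerance = 1e-8)
})

test_that("exchangeable weighting agrees with compound-symmetry GLS", {
  skip_if_not_installed("nlme")
  # Model 3 contains both cluster covariates, so exchangeable weighting is a
  # correctly specified GLS problem and the two solvers must agree
  cfg <- config_confounded(n_pairs = 300)
  sc <- latent_scores(cfg, seed = 6)
  de <- build_double_entry(sc, "x", "y")
  fit <- fit_gee(de, c("x_self", "x_cotwin"), corstr = "exchangeable")
  g <- nlme::gls(y_self ~ x_self + x_cotwin, data = de,
                 correlation = nlme::corCompSymm(form = ~1 | cluster))
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 5e-3)
  rho_gls <- coef(g$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(unname(fit$working_correlation), unname(rho_gls),
               tolerance = 0.03)
})

test_that("degenerate designs and empty terms are rejected", {
  cfg <- config_confounded(n_pairs = 50)
  sc <- latent_scores(cfg, seed = 7)
  de <- build_double_entry(sc, "x", "y")
  expect_error(fit_gee(de, character(0)), "non-empty")
  expect_error(fit_gee(de, "nope"), "unknown term")
  de$x_cotwin <- de$x_self
  expect_error(fit_gee(de, c("x_self", "x_cotwin")), "singular")
})

test_that("few clusters trigger a warning", {
  sc <- four_pair_scores()
  sc$x <- sc$x + rnorm(8, 0, 0.1)
  expect_warning(fit_gee(build_double_entry(sc, "x", "y"), "x_self"),
                 "clusters")
})

test_that("tidy and glance expose the fit in broom shape", {
  cfg <- config_confounded(n_pairs = 80)
  sc <- latent_scores(cfg, seed = 8)
  fit <- fit_gee(build_double_entry(sc, "x", "y"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value"))
  expect_equal(nrow(td), 3)
  expect_true(all(td$p.value > 0 & td$p.value <= 1))
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 80L)
})
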