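#' Simulate monozygotic twin-pair trait data
#'
#' Draws complete MZ twin pairs from the linear structural model described by
#' a [sim_config()]: for each pair, pair-shared trait-specific components and
#' latent confounders are drawn once and given to both twins, individual
#' components are drawn per twin, within-person causal paths are resolved
#' through the reduced form, an age effect is added, and each latent trait is
#' carried to its raw observation scale.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`. The same seed
#'   always yields an identical dataset.
#' @return A tibble with one row per twin: `pair_id`, `twin_index` (1 or 2),
#'   `age` (years at mammography), one column per trait on the raw scale,
#'   and `stratifier` if configured.
#' @examples
#' cfg <- sim_config(50, c("x", "y"), paths = c("x->y" = 0.4),
#'                   familial_loading = c(x = 0.6, y = 0.3),
#'                   unique_sd = c(x = 0.8, y = 0.8))
#' simulate_pairs(cfg)
#' @export
simulate_pairs <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(seed %||% config$seed)
  n <- config$n_pairs
  traits <- config$traits
  p <- length(traits)
  B <- path_matrix(config)
  M <- solve(diag(p) - B)
  L <- confounder_matrix(config)
  k <- ncol(L)

  Fam <- matrix(rnorm(n * p), n, p) %*% diag(config$familial_loading, p)
  Conf <- if (k > 0) matrix(rnorm(n * k), n, k) else matrix(0, n, 0)
  shared <- Fam + (if (k > 0) Conf %*% t(L) else 0)
  e1 <- matrix(rnorm(n * p), n, p) %*% diag(config$unique_sd, p)
  e2 <- matrix(rnorm(n * p), n, p) %*% diag(config$unique_sd, p)
  y1 <- (shared + e1) %*% t(M)
  y2 <- (shared + e2) %*% t(M)
  colnames(y1) <- colnames(y2) <- traits

  age_pair <- runif(n, config$age_range[1], config$age_range[2])
  age1 <- age_pair + rnorm(n, 0, config$age_jitter_sd)
  age2 <- age_pair + rnorm(n, 0, config$age_jitter_sd)
  mid <- mean(config$age_range)

  raw_one <- function(y, age) {
    out <- lapply(traits, function(tr) {
      u <- y[, tr] + config$age_slope[[tr]] * (age - mid)
      apply_raw_transform(u, config$raw_transforms[[tr]])
    })
    names(out) <- traits
    out
  }
  r1 <- raw_one(y1, age1)
  r2 <- raw_one(y2, age2)

  strat <- NULL
  if (!is.null(config$stratifier)) {
    st <- config$stratifier
    lo <- rep(0, p)
    names(lo) <- traits
    lo[names(st$loadings)] <- unlist(st$loadings)
    base <- as.vector(((y1 + y2) / 2) %*% lo) +
      rnorm(n, 0, st$noise_sd %||% 0.5)
    strat <- (st$mean %||% 0) + (st$scale %||% 1) * base
  }

  d1 <- tibble::tibble(pair_id = seq_len(n), twin_index = 1L, age = age1,
                       !!!r1)
  d2 <- tibble::tibble(pair_id = seq_len(n), twin_index = 2L, age = age2,
                       !!!r2)
  if (!is.null(strat)) {
    d1$stratifier <- strat
    d2$stratifier <- strat
  }
  dplyr::arrange(dplyr::bind_rows(d1, d2), .data$pair_id, .data$twin_index)
}

#' Read or write a twin-pair dataset as CSV
#'
#' Plain-CSV serialisation of the long-format twin-pair table produced by
#' [simulate_pairs()]: `pair_id`, `twin_index`, `age`, one column per trait,
#' optional `stratifier`.
#'
#' @param data Tibble of twin-pair rows.
#' @param path CSV file path.
#' @return `read_pairs()` returns a tibble; `write_pairs()` returns `path`
#'   invisibly.
#' @export
write_pairs <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

# Complete-pair filter: keeps pairs with both twins present and no missing
# values in the used columns; reports how many pairs were dropped.
complete_pairs <- function(data, cols) {
  ok_rows <- complete.cases(data[, cols, drop = FALSE])
  counts <- table(data$pair_id[ok_rows])
  keep_ids <- as.numeric(names(counts)[counts == 2])
  dropped <- length(unique(data$pair_id)) - length(keep_ids)
  if (dropped > 0) {
    inform(sprintf("dropped %d incomplete pair(s)", dropped))
  }
  out <- data[ok_rows & data$pair_id %in% keep_ids, , drop = FALSE]
  dplyr::arrange(out, .data$pair_id, .data$twin_index)
}
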