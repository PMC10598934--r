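# shared fixtures: small structural configs and a simulate->score shortcut

config_causal <- function(n_pairs = 200, b = 0.4, seed = 1) {
  sim_config(
    n_pairs = n_pairs, traits = c("x", "y"),
    paths = c("x->y" = b),
    familial_loading = c(x = 0.6, y = 0),
    unique_sd = c(x = 0.8, y = 0.8),
    seed = seed
  )
}

config_confounded <- function(n_pairs = 200, seed = 1) {
  sim_config(
    n_pairs = n_pairs, traits = c("x", "y"),
    familial_loading = c(x = 0.3, y = 0.3),
    unique_sd = c(x = 0.7, y = 0.7),
    confounders = list(shared = c(x = 0.6, y = 0.5)),
    seed = seed
  )
}

config_independent <- function(n_pairs = 200, seed = 1) {
  sim_config(
    n_pairs = n_pairs, traits = c("x", "y"),
    familial_loading = c(x = 0.6, y = 0.5),
    unique_sd = c(x = 0.8, y = 0.9),
    seed = seed
  )
}

latent_scores <- function(config, seed = 1) {
  risk_scores(simulate_pairs(config, seed = seed), config$traits,
              transforms = "identity")
}

# hand-written four-pair score fixture (pairs: (1,2),(2,1),(3,4),(4,3))
four_pair_scores <- function() {
  tibble::tibble(
    pair_id = rep(1:4, each = 2),
    twin_index = rep(1:2, 4),
    x = c(1, 2, 2, 1, 3, 4, 4, 3),
    y = c(2, 1, 1, 2, 4, 3, 3, 4)
  )
}
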