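#' Specify a twin-pair structural simulation
#'
#' Defines a linear-Gaussian structural model for monozygotic twin pairs.
#' Each trait receives a pair-shared trait-specific component, loadings on
#' pair-shared latent confounders, an individual-specific component, and
#' (optionally) directed causal paths from other traits measured on the same
#' individual. Cross-twin causal paths are excluded by construction: a twin's
#' trait never acts causally on her co-twin's traits, so all cross-twin
#' covariance flows through the pair-shared components. Cyclic within-person
#' path systems (e.g. bidirectional causation between two traits) are allowed
#' and are resolved through the reduced form `(I - B)^-1`, which must exist.
#'
#' @param n_pairs Number of complete twin pairs (>= 2).
#' @param traits Character vector of trait names.
#' @param paths Named numeric vector of within-person causal path
#'   coefficients, named `"source->target"`, e.g.
#'   `c("light_areas->bright_areas" = 0.7)`.
#' @param familial_loading Named numeric vector (per trait): standard
#'   deviation of the pair-shared trait-specific component. Defaults to 0.
#' @param unique_sd Named numeric vector (per trait): standard deviation of
#'   the individual-specific component. Must be > 0; defaults to 1.
#' @param confounders Named list of pair-shared latent confounders; each
#'   element is a named numeric vector of loadings per trait.
#' @param age_range Length-2 numeric: uniform range (years) for the
#'   pair-level age at mammography.
#' @param age_slope Named numeric vector (per trait): change in the latent
#'   trait (in latent SD units) per year of age.
#' @param age_jitter_sd Within-pair SD (years) of individual age around the
#'   shared pair age, reflecting mammograms taken at different dates.
#' @param raw_transforms Named list (per trait) describing the monotone map
#'   from the latent scale to the observed raw scale; see
#'   [raw_transform()]. Traits without an entry are observed on the latent
#'   scale directly.
#' @param stratifier Optional list describing a pair-level stratification
#'   variable: `list(loadings = <named numeric per trait>, noise_sd =,
#'   mean =, scale =)`. The stratifier is built from pair means of the
#'   latent traits plus noise.
#' @param seed Integer seed stored with the configuration; used by
#'   [simulate_pairs()] unless overridden.
#'
#' @return A `sim_config` object (a validated list).
#' @seealso [simulate_pairs()], [population_moments()],
#'   [theoretical_coefficients()], [calibrate_pair_config()]
#' @examples
#' cfg <- sim_config(
#'   n_pairs = 100, traits = c("x", "y"),
#'   paths = c("x->y" = 0.4),
#'   familial_loading = c(x = 0.7, y = 0.3),
#'   unique_sd = c(x = 0.7, y = 0.8)
#' )
#' @export
sim_config <- function(n_pairs,
                       traits,
                       paths = NULL,
                       familial_loading = NULL,
                       unique_sd = NULL,
                       confounders = list(),
                       age_range = c(40, 70),
                       age_slope = NULL,
                       age_jitter_sd = 0.5,
                       raw_transforms = NULL,
                       stratifier = NULL,
                       seed = 1L) {
  traits <- as.character(traits)
  fill <- function(x, default) {
    out <- setNames(rep(default, length(traits)), traits)
    if (!is.null(x)) {
      bad <- setdiff(names(x), traits)
      if (length(bad) > 0) {
        abort(paste0("unknown trait(s) in per-trait field: ",
                     paste(bad, collapse = ", ")))
      }
      out[names(x)] <- x
    }
    out
  }
  cfg <- structure(
    list(
      n_pairs = as.integer(n_pairs),
      traits = traits,
      paths = paths %||% setNames(numeric(0), character(0)),
      familial_loading = fill(familial_loading, 0),
      unique_sd = fill(unique_sd, 1),
      confounders = confounders,
      age_range = as.numeric(age_range),
      age_slope = fill(age_slope, 0),
      age_jitter_sd = age_jitter_sd,
      raw_transforms = raw_transforms %||% list(),
      stratifier = stratifier,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_pairs, " MZ pairs, traits: ",
      paste(x$traits, collapse = ", "), "\n", sep = "")
  if (length(x$paths) > 0) {
    cat("  causal paths: ",
        paste(sprintf("%s (%.3g)", names(x$paths), x$paths), collapse = ", "),
        "\n", sep = "")
  }
  cat("  familial sd: ",
      paste(sprintf("%s=%.3g", x$traits, x$familial_loading), collapse = ", "),
      "; unique sd: ",
      paste(sprintf("%s=%.3g", x$traits, x$unique_sd), collapse = ", "),
      "\n", sep = "")
  if (length(x$confounders) > 0) {
    cat("  shared confounders: ", paste(names(x$confounders), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Path matrix B with B[target, source]; reduced form is (I - B)^-1.
path_matrix <- function(config) {
  p <- length(config$traits)
  B <- matrix(0, p, p, dimnames = list(config$traits, config$traits))
  if (length(config$paths) > 0) {
    parts <- strsplit(names(config$paths), "->", fixed = TRUE)
    for (i in seq_along(parts)) {
      pr <- trimws(parts[[i]])
      if (length(pr) != 2 || !all(pr %in% config$traits)) {
        abort(paste0("malformed or unknown causal path: ",
                     names(config$paths)[i]))
      }
      B[pr[2], pr[1]] <- config$paths[[i]]
    }
  }
  B
}

# Loading matrix of pair-shared latent confounders (traits x confounders).
confounder_matrix <- function(config) {
  p <- length(config$traits)
  k <- length(config$confounders)
  L <- matrix(0, p, max(k, 1), dimnames = list(config$traits, NULL))
  if (k == 0) return(L[, 0, drop = FALSE])
  for (j in seq_len(k)) {
    lo <- config$confounders[[j]]
    bad <- setdiff(names(lo), config$traits)
    if (length(bad) > 0) {
      abort(paste0("confounder '", names(config$confounders)[j],
                   "' loads on unknown trait(s): ", paste(bad, collapse = ", ")))
    }
    L[names(lo), j] <- lo
  }
  colnames(L) <- names(config$confounders)
  L
}

validate_sim_config <- function(config) {
  if (config$n_pairs < 2) abort("n_pairs must be >= 2")
  if (any(config$unique_sd <= 0)) abort("all unique_sd must be > 0")
  if (any(config$familial_loading < 0)) abort("familial_loading must be >= 0")
  if (length(config$age_range) != 2 || diff(config$age_range) < 0) {
    abort("age_range must be c(min, max) with min <= max")
  }
  B <- path_matrix(config)
  if (length(config$paths) > 0) {
    sr <- max(Mod(eigen(B, only.values = TRUE)$values))
    if (sr >= 1) {
      abort(paste0(
        "structural system is non-invertible (spectral radius ",
        sprintf("%.3f", sr), " >= 1); cyclic paths: ",
        paste(names(config$paths), collapse = ", ")
      ))
    }
  }
  bad_tr <- setdiff(names(config$raw_transforms), config$traits)
  if (length(bad_tr) > 0) {
    abort(paste0("raw_transforms for unknown trait(s): ",
                 paste(bad_tr, collapse = ", ")))
  }
  config
}

#' Describe the map from the latent scale to an observed raw scale
#'
#' The simulator draws each trait as a standardised latent normal score and
#' then carries it to a skewed raw scale through a monotone power map:
#' `raw = offset + (center + scale * u)^power`, where `u` is the latent score
#' plus the age effect. The analysis-side normalising transform is the
#' inverse: `(raw - offset)^(1/power)` is linear in the latent score, so a
#' Box-Cox fit on the raw values should recover `lambda = 1/power`.
#'
#' @param power Exponent of the raw map (3 for a cube, 5 for a fifth power,
#'   1/2 for a square-root-plus-shift scale).
#' @param offset Constant added on the raw scale (e.g. 2907 for a
#'   Cirrus-like score).
#' @param center,scale Location and spread of the transformed scale; chosen
#'   so that `center + scale * u` stays positive for all plausible `u`.
#' @return A `raw_transform` list.
#' @export
raw_transform <- function(power, offset = 0, center = 5, scale = 1) {
  if (scale <= 0 || center <= 0) abort("center and scale must be > 0")
  structure(list(power = power, offset = offset, center = center,
                 scale = scale), class = "raw_transform")
}

# u -> raw; the tiny positive floor keeps raw area measures strictly
# positive in the extreme lower tail (monotonicity elsewhere is exact).
apply_raw_transform <- function(u, tr) {
  if (is.null(tr)) return(u)
  t_scale <- pmax(tr$center + tr$scale * u, 0.01 * tr$center)
  tr$offset + t_scale^tr$power
}

#' Raw-scale transforms emulating mammographic density measures
#'
#' Returns `raw_transform`s for four mammogram-based risk measures: light
#' and bright dense areas (cube-scale, cm^2), brightest areas (fifth-power
#' scale, cm^2), and a Cirrus-like texture score (square-root scale shifted
#' by 2907). Locations and spreads are set so the simulated raw medians and
#' quartiles resemble screening-age mammograms.
#'
#' @return Named list of [raw_transform()] objects.
#' @export
mammographic_transforms <- function() {
  list(
    light_areas    = raw_transform(power = 3,   offset = 0,    center = 2.59,  scale = 0.59),
    bright_areas   = raw_transform(power = 3,   offset = 0,    center = 2.07,  scale = 0.42),
    brightest_areas = raw_transform(power = 5,  offset = 0,    center = 1.10,  scale = 0.23),
    cirrus         = raw_transform(power = 0.5, offset = 2907, center = 11.56, scale = 3.66)
  )
}

#' Normalising transform specifications matching the raw-scale maps
#'
#' The exact analysis-side inverses of [mammographic_transforms()]: cube
#' root for light and bright areas, fifth root for brightest areas, and
#' `(x - 2907)^2` for the Cirrus-like score.
#'
#' @return Named list of [transform_spec()] objects.
#' @export
mammographic_transform_specs <- function() {
  list(
    light_areas     = transform_spec("light_areas", shift = 0, lambda = 1 / 3),
    bright_areas    = transform_spec("bright_areas", shift = 0, lambda = 1 / 3),
    brightest_areas = transform_spec("brightest_areas", shift = 0, lambda = 1 / 5),
    cirrus          = transform_spec("cirrus", shift = -2907, lambda = 2)
  )
}

age_slope_for_r2 <- function(r2, age_range = c(40, 70), age_jitter_sd = 0.5) {
  v_age <- diff(age_range)^2 / 12 + age_jitter_sd^2
  sqrt(r2 / (1 - r2) / v_age)
}

#' Calibrate a two-trait twin simulation to a target correlation structure
#'
#' Solves, in closed form, for a structural configuration (one directed path
#' `x -> y`, one pair-shared confounder loading on both traits, trait-specific
#' familial components) whose population correlation structure matches the
#' four targets exactly: the within-pair correlation of each trait, the
#' within-twin cross-trait correlation, and the cross-twin cross-trait
#' correlation. Both traits have unit population variance, so the targets are
#' reproduced on the standardised risk-score scale.
#'
#' @param trait_x,trait_y Trait names (`trait_x` is the path source).
#' @param rho_x,rho_y Target within-pair correlations of each trait.
#' @param r_within Target within-twin cross-trait correlation
#'   (`x_self` with `y_self`).
#' @param r_cross Target cross-twin cross-trait correlation
#'   (`x_self` with `y_cotwin`).
#' @param n_pairs,seed Passed to [sim_config()].
#' @param age_r2 Named numeric (per trait): fraction of transformed-scale
#'   variance explained by age; converted to an age slope internally.
#' @param raw_transforms,stratifier Passed to [sim_config()].
#' @return A `sim_config` whose [population_moments()] reproduce the targets.
#' @examples
#' cfg <- calibrate_pair_config("light_areas", "bright_areas",
#'   rho_x = 0.59, rho_y = 0.53, r_within = 0.81, r_cross = 0.52,
#'   n_pairs = 371
#' )
#' @export
calibrate_pair_config <- function(trait_x, trait_y,
                                  rho_x, rho_y, r_within, r_cross,
                                  n_pairs = 371,
                                  seed = 1L,
                                  age_r2 = NULL,
                                  raw_transforms = NULL,
                                  stratifier = NULL) {
  if (rho_x <= 0 || rho_x >= 1 || rho_y <= 0 || rho_y >= 1) {
    abort("rho_x and rho_y must lie strictly between 0 and 1")
  }
  b <- (r_within - r_cross) / (1 - rho_x)
  q <- r_within - b # confounded covariance between x and y
  cx <- sqrt(rho_x / 2)
  ax <- cx
  ex <- sqrt(1 - rho_x)
  cy <- q / cx
  ay2 <- rho_y - (b^2 * rho_x + 2 * b * q + cy^2)
  if (ay2 < 0) {
    abort(sprintf(
      "targets infeasible under this structural family (ay^2 = %.4f < 0)", ay2))
  }
  ey2 <- 1 - (b^2 + 2 * b * q + ay2 + cy^2)
  if (ey2 <= 0) {
    abort(sprintf(
      "targets infeasible under this structural family (ey^2 = %.4f <= 0)", ey2))
  }
  slopes <- NULL
  if (!is.null(age_r2)) {
    slopes <- vapply(age_r2, age_slope_for_r2, numeric(1))
    # density declines with age
    slopes <- -abs(slopes)
  }
  paths <- setNames(b, paste0(trait_x, "->", trait_y))
  if (b == 0) paths <- NULL
  sim_config(
    n_pairs = n_pairs,
    traits = c(trait_x, trait_y),
    paths = paths,
    familial_loading = setNames(c(ax, sqrt(ay2)), c(trait_x, trait_y)),
    unique_sd = setNames(c(ex, sqrt(ey2)), c(trait_x, trait_y)),
    confounders = list(shared = setNames(c(cx, cy), c(trait_x, trait_y))),
    age_slope = slopes,
    raw_transforms = raw_transforms,
    stratifier = stratifier,
    seed = seed
  )
}

#' Read or write a simulation configuration file
#'
#' Serialises a `sim_config` to YAML (or JSON, chosen by file extension) and
#' back. Raw transforms and confounder loadings survive the round trip.
#'
#' @param config A `sim_config`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$paths <- as.list(x$paths)
  x$familial_loading <- as.list(x$familial_loading)
  x$unique_sd <- as.list(x$unique_sd)
  x$age_slope <- as.list(x$age_slope)
  x$confounders <- lapply(x$confounders, as.list)
  x$raw_transforms <- lapply(x$raw_transforms, unclass)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_sim_config(x)
}

#' @rdname write_sim_config
#' @param x A list with `sim_config` fields (e.g. parsed from YAML).
#' @export
as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  sim_config(
    n_pairs = x$n_pairs,
    traits = x$traits,
    paths = if (length(x$paths) > 0) unlist(x$paths) else NULL,
    familial_loading = unlist(x$familial_loading),
    unique_sd = unlist(x$unique_sd),
    confounders = lapply(x$confounders %||% list(), unlist),
    age_range = x$age_range %||% c(40, 70),
    age_slope = unlist(x$age_slope),
    age_jitter_sd = x$age_jitter_sd %||% 0.5,
    raw_transforms = lapply(x$raw_transforms %||% list(), function(tr) {
      raw_transform(tr$power, tr$offset %||% 0, tr$center %||% 5,
                    tr$scale %||% 1)
    }),
    stratifier = x$stratifier,
    seed = x$seed %||% 1L
  )
}
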