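#' Default model configuration
#'
#' Returns the shipped calibration of the foraging model. Values fixed by the
#' model definition are the normal regrowth rate (1 food unit/tick), the
#' shocked regrowth rate (0.1 food units/tick), the mutation kernel (a 20%
#' chance of the offspring gene moving down by 0.1 and a 20% chance of moving
#' up, steps leaving \[0, 1\] cancelled), the 0.1 gene step, and the run
#' length of 20,000 ticks. All remaining values are calibration choices; every
#' one of them is exposed here so that sweeps can adjust them.
#'
#' @return A named list of class `sim_config` containing all model
#'   parameters. See the package vignette for the meaning and units of each.
#' @examples
#' cfg <- default_config()
#' cfg$run_length
#' @export
default_config <- function() {
  cfg <- list(
    # world
    grid_width = 56L,
    grid_height = 56L,
    max_food_per_patch = 10,
    regrowth_normal = 1,
    regrowth_shocked = 0.1,
    recovery_prob = 0.016,
    n_predator_patches = 24L,
    # agent physiology
    food_to_energy = 1,
    energy_capacity = 100,
    storage_capacity = 50,
    living_cost = 0.5,
    refill_threshold = 5,
    # reproduction
    repro_energy_fraction = 0.45,
    repro_age_min = 15L,
    repro_age_max = 60L,
    birth_cost = 10,
    birth_transfer = 20,
    # mortality
    old_age_threshold = 60L,
    old_age_death_prob = 0.05,
    # mutation kernel
    mutation_step = 0.1,
    mutation_down_prob = 0.2,
    mutation_up_prob = 0.2,
    # sharing practice
    share_donor_store_fraction = 0.5,
    share_recipient_energy_multiple = 20,
    share_amount = 10,
    share_radius = 3L,
    innovation_prob = 0.05,
    # within-lifetime adaptation
    vicinity_radius = 3L,
    ledger_window = 30L,
    ledger_skew_threshold = 1L,
    # initialisation
    init_population = 400L,
    init_energy_range = c(25, 75),
    init_food_range = c(0, 10),
    # run control
    run_length = 20000L,
    shock_tick = 10000L,
    # outcome measure
    wellbeing_energy_multiple = 2
  )
  structure(cfg, class = "sim_config")
}

config_keys <- function() names(unclass(default_config()))

#' Validate a model configuration
#'
#' Checks types, ranges, and cross-field invariants: probabilities in
#' \[0, 1\], non-negative counts and capacities, `regrowth_shocked <
#' regrowth_normal`, `mutation_down_prob + mutation_up_prob <= 1`,
#' `repro_age_min < repro_age_max`, and fewer predator patches than grid
#' cells.
#'
#' @param config A `sim_config` or plain named list with the full key set.
#' @return The validated config (invisibly classed `sim_config`).
#' @export
validate_config <- function(config) {
  keys <- config_keys()
  missing <- setdiff(keys, names(config))
  if (length(missing) > 0)
    stop("config is missing keys: ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(config), keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))

  bad <- character(0)
  num1 <- function(k) {
    v <- config[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) bad <<- c(bad, k)
    v
  }
  prob <- function(k) {
    v <- num1(k)
    if (is.numeric(v) && length(v) == 1 && !is.na(v) && (v < 0 || v > 1))
      bad <<- c(bad, k)
    v
  }
  nonneg <- function(k) {
    v <- num1(k)
    if (is.numeric(v) && length(v) == 1 && !is.na(v) && v < 0)
      bad <<- c(bad, k)
    v
  }
  pos <- function(k) {
    v <- num1(k)
    if (is.numeric(v) && length(v) == 1 && !is.na(v) && v <= 0)
      bad <<- c(bad, k)
    v
  }

  pos("grid_width"); pos("grid_height")
  pos("max_food_per_patch")
  nonneg("regrowth_normal"); nonneg("regrowth_shocked")
  prob("recovery_prob")
  nonneg("n_predator_patches")
  pos("food_to_energy"); pos("energy_capacity"); nonneg("storage_capacity")
  nonneg("living_cost"); nonneg("refill_threshold")
  prob("repro_energy_fraction")
  nonneg("repro_age_min"); nonneg("repro_age_max")
  nonneg("birth_cost"); nonneg("birth_transfer")
  nonneg("old_age_threshold")
  prob("old_age_death_prob")
  pos("mutation_step")
  prob("mutation_down_prob"); prob("mutation_up_prob")
  prob("share_donor_store_fraction")
  nonneg("share_recipient_energy_multiple")
  nonneg("share_amount"); nonneg("share_radius")
  prob("innovation_prob")
  nonneg("vicinity_radius"); pos("ledger_window")
  nonneg("ledger_skew_threshold")
  nonneg("init_population")
  nonneg("run_length"); nonneg("shock_tick")
  nonneg("wellbeing_energy_multiple")

  for (k in c("init_energy_range", "init_food_range")) {
    v <- config[[k]]
    if (!is.numeric(v) || length(v) != 2 || any(is.na(v)) ||
        v[1] > v[2] || v[1] < 0) bad <- c(bad, k)
  }

  if (length(bad) > 0)
    stop("invalid config values for: ", paste(unique(bad), collapse = ", "))

  if (config$regrowth_shocked >= config$regrowth_normal)
    stop("invalid config values for: regrowth_shocked ",
         "(must be < regrowth_normal)")
  if (config$mutation_down_prob + config$mutation_up_prob > 1 + 1e-12)
    stop("invalid config values for: mutation_down_prob, mutation_up_prob ",
         "(must sum to at most 1)")
  if (config$repro_age_min >= config$repro_age_max)
    stop("invalid config values for: repro_age_min, repro_age_max ",
         "(min must be < max)")
  if (config$n_predator_patches >= config$grid_width * config$grid_height)
    stop("invalid config values for: n_predator_patches ",
         "(must be < grid_width * grid_height)")

  invisible(structure(config[keys], class = "sim_config"))
}

#' Load a configuration from a YAML file
#'
#' Reads a flat key-value YAML file. Keys present override the shipped
#' defaults; keys absent keep their default value; unknown keys are an error
#' (not a warning) to protect calibration reproducibility. An empty file
#' yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @seealso [save_config()], [default_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must be a YAML mapping: ", path)
  unknown <- setdiff(names(vals), config_keys())
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(unclass(default_config()), vals)
  validate_config(cfg)
}

#' Save a configuration to a YAML file
#'
#' The written file round-trips through [load_config()] to an identical
#' configuration (all fields, including two-element ranges).
#'
#' @param config A `sim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Apply `key=value` overrides to a configuration
#'
#' Convenience used by the command-line interface's `--set` flag and by
#' calibration sweeps.
#'
#' @param config A `sim_config`.
#' @param overrides Named list (or character vector of `"key=value"` strings)
#'   of replacement values.
#' @return A validated `sim_config`.
#' @export
config_override <- function(config, overrides) {
  if (is.character(overrides)) {
    parts <- strsplit(overrides, "=", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("overrides must be key=value pairs")
    vals <- lapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2]))
      if (is.na(v)) stop("override value is not numeric: ", p[2])
      v
    })
    names(vals) <- vapply(parts, `[`, "", 1)
    overrides <- vals
  }
  unknown <- setdiff(names(overrides), config_keys())
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  validate_config(utils::modifyList(unclass(config), overrides))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-32s %s\n", k, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
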