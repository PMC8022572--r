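#' Initialise the patch world (and starting population)
#'
#' Builds the torus grid: every non-predator patch receives an integer food
#' level drawn uniformly from `init_food_range`; exactly
#' `n_predator_patches` distinct patches are flagged as predator patches
#' (their food is fixed at 0 and never changes); no patch starts denuded;
#' the tick counter is 0 and regrowth is at the normal rate. The starting
#' population is placed uniformly on non-predator patches with genes drawn
#' uniformly from the 0.1 grid, energies uniform on `init_energy_range`,
#' age 0, and empty stores.
#'
#' @param config A validated `sim_config`.
#' @param scenario A `scenario_spec` (controls whether predator patches
#'   exist); default is the baseline.
#' @param seed Integer RNG seed.
#' @return A `sim_state` list with elements `world` (food / denuded /
#'   predator matrices, regrowth rate, tick) and `agents` (a list of
#'   per-agent vectors).
#' @export
init_state <- function(config, scenario = scenario_spec("genetic"), seed = 1L) {
  config <- validate_config(config)
  set.seed(seed)
  res <- sim_run_cpp(unclass(config), scenario_flags(scenario), NULL,
                     0L, FALSE, FALSE)
  structure(list(world = res$world, agents = res$agents),
            class = "sim_state")
}

#' @rdname init_state
#' @export
init_world <- function(config, scenario = scenario_spec("genetic"),
                       seed = 1L) {
  init_state(config, scenario, seed)$world
}

#' Advance the environment by one tick (no agents)
#'
#' Each non-denuded, non-predator patch gains the current regrowth rate of
#' food, capped at the patch maximum. Each denuded patch recovers with
#' probability `recovery_prob`; a recovered patch restarts at food 0 and
#' resumes growth from the next tick.
#'
#' @param world A world list as returned by [init_world()].
#' @param config A `sim_config`.
#' @return The updated world (tick incremented).
#' @export
step_environment <- function(world, config) {
  config <- validate_config(config)
  state <- list(world = world, agents = empty_agents())
  res <- sim_run_cpp(unclass(config), scenario_flags(scenario_spec("custom")),
                     state, 1L, FALSE, FALSE)
  res$world
}

empty_agents <- function() {
  list(id = integer(0), x = integer(0), y = integer(0),
       frac = numeric(0), energy = numeric(0), store = numeric(0),
       age = integer(0), sharer = logical(0))
}

#' Apply the regrowth shock to a world
#'
#' Sets the regrowth rate to `regrowth_shocked` for all subsequent ticks.
#' Idempotent. During a full run the engine applies this automatically at
#' `shock_tick` when the scenario includes the shock.
#'
#' @inheritParams step_environment
#' @return The world with the shocked regrowth rate.
#' @export
apply_shock <- function(world, config) {
  world$regrowth <- config$regrowth_shocked
  world
}

#' Ground cover of a world
#'
#' The fraction of non-predator patches that are not denuded. Predator
#' patches are excluded from both numerator and denominator since their food
#' state is frozen.
#'
#' @param world A world list.
#' @return A fraction in \[0, 1\].
#' @export
ground_cover <- function(world) {
  np <- !world$predator
  if (sum(np) == 0) return(NA_real_)
  sum(np & !world$denuded) / sum(np)
}
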