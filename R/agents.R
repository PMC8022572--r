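#' Construct a single agent
#'
#' Convenience constructor for fixtures and single-operation tests. Agents in
#' a running simulation live inside the engine; this R-level representation
#' mirrors its fields.
#'
#' @param id Integer id.
#' @param x,y Patch coordinates (1-based).
#' @param frac Foraging fraction on the 0.1 grid in \[0, 1\].
#' @param energy Energy level.
#' @param store Carried food.
#' @param age Age in ticks.
#' @param sharer Whether the agent carries the sharing practice.
#' @return A named list of class `sim_agent`.
#' @export
agent <- function(id = 1L, x = 1L, y = 1L, frac = 0.5, energy = 50,
                  store = 0, age = 0L, sharer = FALSE) {
  if (abs(frac * 10 - round(frac * 10)) > 1e-9 || frac < 0 || frac > 1)
    stop("foraging fraction must lie on the 0.1 grid in [0, 1]")
  structure(list(id = as.integer(id), x = as.integer(x), y = as.integer(y),
                 frac = frac, energy = energy, store = store,
                 age = as.integer(age), sharer = isTRUE(sharer)),
            class = "sim_agent")
}

#' Forage from a patch and eat the surplus
#'
#' The agent takes `frac * food` from the patch. What fits goes into the
#' store (up to the storage capacity); the surplus is eaten immediately,
#' converted to energy at `food_to_energy` and capped at the energy capacity
#' (overflow is lost). If the take strips the patch of all its food, the
#' patch becomes denuded.
#'
#' @param agent A `sim_agent`.
#' @param patch A list with elements `food` and `denuded`.
#' @param config A `sim_config`.
#' @return A list with the updated `agent`, `patch`, the amount `eaten`
#'   directly, and the `cap_loss` of energy lost to the capacity ceiling.
#' @examples
#' cfg <- default_config()
#' r <- forage_and_eat(agent(frac = 0.5), list(food = 10, denuded = FALSE), cfg)
#' r$agent$store  # 5
#' @export
forage_and_eat <- function(agent, patch, config) {
  r <- cpp_forage_eat(agent$frac, patch$food, agent$store, agent$energy,
                      unclass(config))
  agent$store <- r$store
  agent$energy <- r$energy
  patch$food <- r$food
  if (r$denuded) patch$denuded <- TRUE
  list(agent = agent, patch = patch, eaten = r$eaten, cap_loss = r$cap_loss)
}

#' Metabolise: pay the living cost and refill from the store
#'
#' Energy drops by `living_cost`. If it falls below `refill_threshold` the
#' agent eats from its store, up to the energy capacity. If energy is still
#' at or below zero the agent dies of exhaustion.
#'
#' @inheritParams forage_and_eat
#' @return A list with the updated `agent`, the food `refilled` from the
#'   store, and `died` (exhaustion).
#' @export
metabolize <- function(agent, config) {
  r <- cpp_metabolize(agent$energy, agent$store, unclass(config))
  agent$energy <- r$energy
  agent$store <- r$store
  list(agent = agent, refilled = r$refill_food, died = r$died)
}

#' Mutate a foraging gene
#'
#' With probability `mutation_down_prob` the gene moves down one step, with
#' `mutation_up_prob` up one step, otherwise it is unchanged. A move that
#' would leave \[0, 1\] is cancelled, so at the boundaries the blocked step's
#' probability mass stays on the parent value.
#'
#' @param value A gene on the 0.1 grid.
#' @param config A `sim_config`.
#' @param n Number of independent draws.
#' @return A numeric vector of `n` mutated genes.
#' @examples
#' set.seed(1)
#' table(mutate_fraction(0.5, default_config(), n = 1000))
#' @export
mutate_fraction <- function(value, config, n = 1L) {
  if (abs(value * 10 - round(value * 10)) > 1e-9 || value < 0 || value > 1)
    stop("gene value must lie on the 0.1 grid in [0, 1]")
  cpp_mutate(value, as.integer(n), unclass(config))
}

#' Move an agent one step on the torus
#'
#' The destination is a uniformly chosen Moore neighbour (8 cells, wrapping).
#' If it is a predator patch the agent dies before foraging.
#'
#' @param agent A `sim_agent`.
#' @param world A world list.
#' @return A list with the updated `agent` and `died` (predation).
#' @export
move_agent <- function(agent, world) {
  w <- nrow(world$food); h <- ncol(world$food)
  moves <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
                 dy = c(-1, -1, -1, 0, 0, 1, 1, 1))
  k <- sample.int(8, 1)
  agent$x <- ((agent$x - 1 + moves[k, "dx"]) %% w) + 1
  agent$y <- ((agent$y - 1 + moves[k, "dy"]) %% h) + 1
  list(agent = agent, died = isTRUE(world$predator[agent$x, agent$y]))
}

#' Attempt reproduction
#'
#' An agent whose age lies in the reproductive window and whose energy has
#' reached `repro_energy_fraction` of the energy capacity produces one
#' offspring: it pays `birth_cost + birth_transfer` energy, of which
#' `birth_transfer` becomes the offspring's starting energy. The offspring
#' starts at the parent's position with age 0, an empty store, a gene drawn
#' from the parent's current gene through the mutation kernel, and the
#' parent's sharer flag. If the payment drives the parent's energy to zero
#' or below, the parent dies of birth; the offspring survives, the transfer
#' having already occurred.
#'
#' @inheritParams forage_and_eat
#' @return A list with the updated `agent`, the `offspring` (or `NULL`), and
#'   `died` (birth).
#' @export
attempt_reproduction <- function(agent, config) {
  eligible <- agent$age >= config$repro_age_min &&
    agent$age <= config$repro_age_max &&
    agent$energy >= config$repro_energy_fraction * config$energy_capacity
  if (!eligible) return(list(agent = agent, offspring = NULL, died = FALSE))
  agent$energy <- agent$energy - config$birth_cost - config$birth_transfer
  offspring <- agent
  offspring$id <- NA_integer_
  offspring$age <- 0L
  offspring$store <- 0
  offspring$energy <- config$birth_transfer
  offspring$frac <- mutate_fraction(agent$frac, config)
  offspring$sharer <- agent$sharer
  list(agent = agent, offspring = offspring, died = agent$energy <= 0)
}

#' Old-age mortality check
#'
#' Above `old_age_threshold` the agent dies with probability
#' `old_age_death_prob` per tick.
#'
#' @inheritParams forage_and_eat
#' @return `TRUE` if the agent dies of old age this tick.
#' @export
check_old_age <- function(agent, config) {
  agent$age > config$old_age_threshold &&
    stats::runif(1) < config$old_age_death_prob
}
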