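# Deterministic mechanism fixtures: tiny hand-built worlds in which one tick
# of the real engine has a single, exactly predictable outcome.  Stochastic
# rules are forced to probability 0 or 1 so the expected post-state is exact.
# The catalogue doubles as the mechanism coverage checklist.

fixture_world <- function(food = 0, denuded = FALSE, predator = FALSE,
                          regrowth = 1, tick = 0L) {
  list(food = matrix(as.numeric(food), 1, 1),
       denuded = matrix(denuded, 1, 1),
       predator = matrix(predator, 1, 1),
       regrowth = regrowth, tick = as.integer(tick))
}

fixture_agents <- function(..., ledger_births = NULL, ledger_deaths = NULL) {
  ags <- list(...)
  out <- list(
    id = vapply(ags, function(a) a$id, integer(1)),
    x = vapply(ags, function(a) a$x, integer(1)),
    y = vapply(ags, function(a) a$y, integer(1)),
    frac = vapply(ags, function(a) a$frac, numeric(1)),
    energy = vapply(ags, function(a) a$energy, numeric(1)),
    store = vapply(ags, function(a) a$store, numeric(1)),
    age = vapply(ags, function(a) a$age, integer(1)),
    sharer = vapply(ags, function(a) a$sharer, logical(1))
  )
  if (!is.null(ledger_births)) {
    out$ledger_births <- ledger_births
    out$ledger_deaths <- ledger_deaths
  }
  out
}

fixture_config <- function(...) {
  # fixed physiology so every expected value below stays exact hand-worked
  # arithmetic, independent of the shipped calibration
  base <- list(grid_width = 1L, grid_height = 1L, n_predator_patches = 0L,
               recovery_prob = 0, innovation_prob = 0, init_population = 0L,
               run_length = 1L,
               living_cost = 1, refill_threshold = 10,
               repro_energy_fraction = 0.6, birth_cost = 15,
               birth_transfer = 25,
               ledger_window = 20L, ledger_skew_threshold = 3L)
  config_override(default_config(), utils::modifyList(base, list(...)))
}

flags_off <- list(shock = FALSE, sharing = FALSE, adaptive = FALSE,
                  predators = TRUE)

#' Names of the mechanism fixture catalogue
#'
#' @return Character vector of the fixture names accepted by
#'   [make_fixture()].
#' @export
fixture_catalogue <- function() {
  c("denude", "recover", "shock", "predation", "refill", "birth",
    "birth-death", "mutation-boundary", "share", "adapt-up", "adapt-down")
}

#' Build one deterministic mechanism fixture
#'
#' Each fixture is a 1-patch world and a scripted agent set for which one
#' tick of the engine has an exactly known outcome: patch denuding, denuded
#' recovery, the regrowth shock, predation, store refill, birth, death in
#' childbirth, the mutation boundary clamp, a sharing transfer, and the two
#' adaptive foraging adjustments. Probabilities are forced to 0 or 1 so no
#' outcome depends on chance.
#'
#' @param name A name from [fixture_catalogue()].
#' @return A list with `name`, `config`, `flags`, `state`, and a `check`
#'   function mapping the raw engine result to a list with `pass`,
#'   `expected`, and `observed`.
#' @export
make_fixture <- function(name) {
  if (!name %in% fixture_catalogue())
    stop("unknown fixture '", name, "'; catalogue: ",
         paste(fixture_catalogue(), collapse = ", "))
  chk <- function(expected, observed)
    list(pass = isTRUE(all.equal(expected, observed, tolerance = 1e-9)),
         expected = expected, observed = observed)
  f <- switch(name,
    "denude" = list(
      config = fixture_config(),
      flags = flags_off,
      state = list(world = fixture_world(food = 4),
                   agents = fixture_agents(agent(frac = 1.0, energy = 50))),
      check = function(res) chk(
        expected = list(denuded = TRUE, food = 0, store = 4, energy = 49),
        observed = list(denuded = res$world$denuded[1, 1],
                        food = res$world$food[1, 1],
                        store = res$agents$store[1],
                        energy = res$agents$energy[1]))),
    "recover" = list(
      config = fixture_config(recovery_prob = 1),
      flags = flags_off,
      state = list(world = fixture_world(food = 0, denuded = TRUE),
                   agents = fixture_agents()),
      check = function(res) chk(
        expected = list(denuded = FALSE, food = 0),
        observed = list(denuded = res$world$denuded[1, 1],
                        food = res$world$food[1, 1]))),
    "shock" = list(
      config = fixture_config(shock_tick = 0L),
      flags = utils::modifyList(flags_off, list(shock = TRUE)),
      state = list(world = fixture_world(food = 3),
                   agents = fixture_agents()),
      check = function(res) chk(
        expected = list(food = 3.1, regrowth = 0.1),
        observed = list(food = res$world$food[1, 1],
                        regrowth = res$world$regrowth))),
    "predation" = list(
      config = fixture_config(),
      flags = flags_off,
      state = list(world = fixture_world(food = 0, predator = TRUE),
                   agents = fixture_agents(agent(energy = 50))),
      check = function(res) chk(
        expected = list(predation_deaths = 1L, survivors = 0L),
        observed = list(
          predation_deaths = unname(res$cause_counts["PREDATION"]),
          survivors = length(res$agents$id)))),
    "refill" = list(
      config = fixture_config(),
      flags = flags_off,
      state = list(world = fixture_world(food = 0),
                   agents = fixture_agents(
                     agent(frac = 0, energy = 5, store = 3))),
      check = function(res) chk(
        expected = list(energy = 7, store = 0),
        observed = list(energy = res$agents$energy[1],
                        store = res$agents$store[1]))),
    "birth" = list(
      config = fixture_config(mutation_down_prob = 0, mutation_up_prob = 0),
      flags = flags_off,
      state = list(world = fixture_world(food = 0),
                   agents = fixture_agents(
                     agent(frac = 0.5, energy = 90, age = 30L))),
      check = function(res) chk(
        expected = list(n = 2L, parent_energy = 49, child_energy = 25,
                        child_frac = 0.5, child_age = 0L),
        observed = list(n = length(res$agents$id),
                        parent_energy = res$agents$energy[1],
                        child_energy = res$agents$energy[2],
                        child_frac = res$agents$frac[2],
                        child_age = res$agents$age[2]))),
    "birth-death" = list(
      config = fixture_config(mutation_down_prob = 0, mutation_up_prob = 0,
                              birth_cost = 30, birth_transfer = 30),
      flags = flags_off,
      state = list(world = fixture_world(food = 0),
                   agents = fixture_agents(
                     agent(frac = 0.5, energy = 61, age = 30L))),
      check = function(res) chk(
        expected = list(birth_deaths = 1L, n = 1L, child_energy = 30,
                        child_age = 0L),
        observed = list(
          birth_deaths = unname(res$cause_counts["BIRTH"]),
          n = length(res$agents$id),
          child_energy = res$agents$energy[1],
          child_age = res$agents$age[1]))),
    "mutation-boundary" = list(
      config = fixture_config(mutation_down_prob = 0, mutation_up_prob = 1),
      flags = flags_off,
      state = list(world = fixture_world(food = 0),
                   agents = fixture_agents(
                     agent(frac = 1.0, energy = 90, age = 30L))),
      check = function(res) chk(
        expected = list(n = 2L, child_frac = 1.0),
        observed = list(n = length(res$agents$id),
                        child_frac = res$agents$frac[2]))),
    "share" = list(
      config = fixture_config(),
      flags = utils::modifyList(flags_off, list(sharing = TRUE)),
      state = list(world = fixture_world(food = 0),
                   agents = fixture_agents(
                     agent(id = 1L, frac = 0, energy = 50, store = 30,
                           sharer = TRUE),
                     agent(id = 2L, frac = 0, energy = 1.5, store = 0))),
      check = function(res) chk(
        expected = list(events = 1L, donor_store = 20,
                        recipient_energy = 10.5),
        observed = list(events = res$n_sharing_events,
                        donor_store = res$agents$store[res$agents$id == 1],
                        recipient_energy =
                          res$agents$energy[res$agents$id == 2]))),
    "adapt-up" = list(
      config = fixture_config(),
      flags = utils::modifyList(flags_off, list(adaptive = TRUE)),
      state = list(world = fixture_world(food = 0),
                   agents = fixture_agents(
                     agent(frac = 0.5, energy = 50),
                     ledger_births = matrix(0L, 1, 20),
                     ledger_deaths = {
                       m <- matrix(0L, 1, 20); m[1, 2] <- 4L; m
                     })),
      check = function(res) chk(
        expected = list(frac = 0.6),
        observed = list(frac = res$agents$frac[1]))),
    "adapt-down" = list(
      config = fixture_config(),
      flags = utils::modifyList(flags_off, list(adaptive = TRUE)),
      state = list(world = fixture_world(food = 0),
                   agents = fixture_agents(
                     agent(frac = 0.5, energy = 50),
                     ledger_births = {
                       m <- matrix(0L, 1, 20); m[1, 2] <- 4L; m
                     },
                     ledger_deaths = matrix(0L, 1, 20))),
      check = function(res) chk(
        expected = list(frac = 0.4),
        observed = list(frac = res$agents$frac[1])))
  )
  f$name <- name
  f
}

#' Run one mechanism fixture through the engine
#'
#' @param fixture A fixture from [make_fixture()] (or its name).
#' @param seed RNG seed (outcomes do not depend on it; draws only order
#'   events).
#' @return The fixture's check result: `pass`, `expected`, `observed`.
#' @export
run_fixture <- function(fixture, seed = 1L) {
  if (is.character(fixture)) fixture <- make_fixture(fixture)
  set.seed(seed)
  res <- sim_run_cpp(unclass(fixture$config), fixture$flags, fixture$state,
                     1L, TRUE, FALSE)
  fixture$check(res)
}

#' Run the whole fixture catalogue
#'
#' @param seed RNG seed forwarded to each fixture.
#' @return A data frame with one row per fixture and a `pass` column.
#' @export
run_fixture_catalogue <- function(seed = 1L) {
  names <- fixture_catalogue()
  pass <- vapply(names, function(n) run_fixture(n, seed)$pass, logical(1))
  data.frame(fixture = names, pass = pass, row.names = NULL)
}
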