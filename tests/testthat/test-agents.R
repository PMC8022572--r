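test_that("foraging splits the take between store and immediate eating", {
  cfg <- classic_config()
  # plain case: half of 10 units fits in the empty store
  r <- forage_and_eat(agent(frac = 0.5, store = 0, energy = 50),
                      list(food = 10, denuded = FALSE), cfg)
  expect_equal(r$agent$store, 5)
  expect_equal(r$patch$food, 5)
  expect_equal(r$agent$energy, 50)
  expect_false(r$patch$denuded)

  # a full take strips and denudes the patch
  r <- forage_and_eat(agent(frac = 1.0), list(food = 7, denuded = FALSE), cfg)
  expect_equal(r$patch$food, 0)
  expect_true(r$patch$denuded)

  # hand-worked split: take 6, store room 4, surplus 2 eaten
  r <- forage_and_eat(agent(frac = 0.6, store = 46, energy = 50),
                      list(food = 10, denuded = FALSE), cfg)
  expect_equal(r$agent$store, 50)
  expect_equal(r$agent$energy, 52)
  expect_equal(r$patch$food, 4)
  expect_equal(r$eaten, 2)

  # a zero gene takes nothing
  r <- forage_and_eat(agent(frac = 0), list(food = 9, denuded = FALSE), cfg)
  expect_equal(r$patch$food, 9)
  expect_equal(r$agent$store, 0)
})

test_that("surplus eating is capped at the energy capacity and the loss reported", {
  cfg <- classic_config()
  r <- forage_and_eat(agent(frac = 1.0, store = cfg$storage_capacity,
                            energy = 99),
                      list(food = 10, denuded = FALSE), cfg)
  expect_equal(r$agent$energy, cfg$energy_capacity)
  expect_equal(r$cap_loss, 9)
})

test_that("metabolism pays the living cost and refills from the store when low", {
  cfg <- classic_config()
  r <- metabolize(agent(energy = 50, store = 0), cfg)
  expect_equal(r$agent$energy, 49)
  expect_false(r$died)

  # hand-worked refill: 10.5 - 1 = 9.5 < 10, store of 3 tops up to 12.5
  r <- metabolize(agent(energy = 10.5, store = 3), cfg)
  expect_equal(r$agent$energy, 12.5)
  expect_equal(r$agent$store, 0)
  expect_equal(r$refilled, 3)

  # exhaustion with an empty store
  r <- metabolize(agent(energy = 0.5, store = 0), cfg)
  expect_true(r$died)
})

test_that("the mutation kernel matches its probabilities and clamps at the edges", {
  cfg <- classic_config()
  n <- 10000
  set.seed(7)
  draws <- mutate_fraction(0.5, cfg, n = n)
  freq <- table(factor(draws, levels = c("0.4", "0.5", "0.6"))) / n
  for (i in seq_along(c(0.2, 0.6, 0.2))) {
    p <- c(0.2, 0.6, 0.2)[i]
    half <- qnorm(0.995) * sqrt(p * (1 - p) / n)
    expect_gt(freq[i], p - half)
    expect_lt(freq[i], p + half)
  }
  # boundary: the blocked downward move stays on the parent value
  draws0 <- mutate_fraction(0, cfg, n = n)
  expect_setequal(unique(draws0), c(0, 0.1))
  p0 <- mean(draws0 == 0)
  expect_gt(p0, 0.8 - qnorm(0.995) * sqrt(0.8 * 0.2 / n))
  expect_lt(p0, 0.8 + qnorm(0.995) * sqrt(0.8 * 0.2 / n))
  expect_true(all(mutate_fraction(1, cfg, n = 1000) %in% c(0.9, 1.0)))
  expect_error(mutate_fraction(0.55, cfg), "grid")
})

test_that("reproduction follows the age window, threshold, and energy ledger", {
  cfg <- classic_config()
  r <- attempt_reproduction(agent(age = 30L, energy = 90, frac = 0.5), cfg)
  expect_false(is.null(r$offspring))
  expect_equal(r$agent$energy, 50)
  expect_equal(r$offspring$energy, 25)
  expect_equal(r$offspring$age, 0L)
  expect_false(r$died)

  # below the age window nothing happens regardless of energy
  r <- attempt_reproduction(agent(age = 5L, energy = 100), cfg)
  expect_null(r$offspring)

  # paying exactly all remaining energy kills the parent, not the child
  cfg2 <- classic_config(birth_cost = 30, birth_transfer = 30)
  r <- attempt_reproduction(agent(age = 30L, energy = 60), cfg2)
  expect_true(r$died)
  expect_false(is.null(r$offspring))
  expect_equal(r$offspring$energy, 30)
})

test_that("movement stays in the Moore neighbourhood and is uniform over it", {
  w <- list(food = matrix(5, 40, 40), denuded = matrix(FALSE, 40, 40),
            predator = matrix(FALSE, 40, 40))
  set.seed(11)
  n <- 10000
  from <- agent(x = 1L, y = 1L)  # corner, so wrapping is exercised
  dest <- t(replicate(n, {
    a <- move_agent(from, w)$agent
    c(a$x, a$y)
  }))
  keys <- paste(dest[, 1], dest[, 2])
  expected <- c("40 40", "1 40", "2 40", "40 1", "2 1", "40 2", "1 2", "2 2")
  expect_setequal(unique(keys), expected)
  half <- qnorm(0.995) * sqrt((1 / 8) * (7 / 8) / n)
  freq <- table(keys) / n
  expect_true(all(freq > 1 / 8 - half & freq < 1 / 8 + half))
})

test_that("old-age mortality applies only above the threshold", {
  cfg <- classic_config()
  set.seed(3)
  expect_false(any(replicate(200, check_old_age(agent(age = 60L), cfg))))
  cfg2 <- classic_config(old_age_death_prob = 1)
  expect_true(check_old_age(agent(age = 61L), cfg2))
})

test_that("foraging genes stay on the 0.1 grid for a whole run", {
  cfg <- small_config()
  log <- run_simulation(cfg, scenario_spec("genetic"), seed = 9)
  fr <- log$final_state$agents$frac
  expect_true(all(abs(fr * 10 - round(fr * 10)) < 1e-9))
  fr_ev <- log$events$frac
  expect_true(all(abs(fr_ev * 10 - round(fr_ev * 10)) < 1e-9))
})

test_that("death records partition all deaths by exactly one cause", {
  cfg <- small_config()
  log <- run_simulation(cfg, scenario_spec("genetic"), seed = 4)
  deaths <- log$events[log$events$event == "DEATH", ]
  expect_equal(nrow(deaths), sum(log$cause_counts))
  expect_true(all(deaths$cause %in%
                    c("OLD_AGE", "EXHAUSTION", "PREDATION", "BIRTH")))
  tallies <- table(factor(deaths$cause, levels = names(log$cause_counts)))
  expect_equal(as.integer(tallies), as.integer(log$cause_counts))
  # no agent appears in the stream after its death
  for (id in utils::head(deaths$id, 25)) {
    expect_lte(sum(log$events$id == id & log$events$event == "DEATH"), 1)
  }
})
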