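test_that("world initialisation obeys the config and the seed", {
  cfg <- default_config()
  w <- init_world(cfg, seed = 1)
  expect_equal(sum(w$predator), cfg$n_predator_patches)
  food <- w$food[!w$predator]
  expect_true(all(food >= cfg$init_food_range[1] &
                    food <= cfg$init_food_range[2]))
  expect_true(all(food == round(food)))
  expect_false(any(w$denuded))
  expect_equal(w$regrowth, cfg$regrowth_normal)
  # determinism under the seed
  expect_identical(w, init_world(cfg, seed = 1))
  expect_false(identical(w$food, init_world(cfg, seed = 2)$food))
})

test_that("regrowth adds the regime rate and caps at the patch maximum", {
  cfg <- classic_config(grid_width = 1L, grid_height = 1L,
                        n_predator_patches = 0L, recovery_prob = 0)
  w <- one_patch_world(food = 3)
  expect_equal(step_environment(w, cfg)$food[1, 1], 4)
  w$food[1, 1] <- cfg$max_food_per_patch
  expect_equal(step_environment(w, cfg)$food[1, 1], cfg$max_food_per_patch)
  # shocked regime grows back a tenth of a unit
  ws <- apply_shock(one_patch_world(food = 3), cfg)
  expect_equal(step_environment(ws, cfg)$food[1, 1], 3.1)
})

test_that("a denuded patch stays at zero food until it recovers", {
  cfg <- classic_config(grid_width = 1L, grid_height = 1L,
                        n_predator_patches = 0L, recovery_prob = 0)
  w <- one_patch_world(food = 0, denuded = TRUE)
  set.seed(1)
  for (i in 1:20) w <- step_environment(w, cfg)
  expect_true(w$denuded[1, 1])
  expect_equal(w$food[1, 1], 0)

  cfg$recovery_prob <- 1
  w2 <- step_environment(one_patch_world(food = 0, denuded = TRUE), cfg)
  expect_false(w2$denuded[1, 1])
  expect_equal(w2$food[1, 1], 0)  # growth resumes only from the next tick
})

test_that("observed recovery frequency matches recovery_prob", {
  p <- 0.01
  cfg <- config_override(default_config(), list(
    grid_width = 20L, grid_height = 20L, n_predator_patches = 0L,
    recovery_prob = p))
  w <- list(food = matrix(0, 20, 20), denuded = matrix(TRUE, 20, 20),
            predator = matrix(FALSE, 20, 20), regrowth = 1, tick = 0L)
  set.seed(42)
  trials <- 0; recoveries <- 0
  for (i in 1:50) {
    n_den <- sum(w$denuded)
    w2 <- step_environment(w, cfg)
    trials <- trials + n_den
    recoveries <- recoveries + (n_den - sum(w2$denuded))
    w2$denuded[] <- TRUE; w2$food[] <- 0  # reset so all patches stay at risk
    w <- w2
  }
  ci <- qnorm(c(0.005, 0.995), mean = p, sd = sqrt(p * (1 - p) / trials))
  expect_gt(recoveries / trials, ci[1])
  expect_lt(recoveries / trials, ci[2])
})

test_that("ground cover excludes predator patches from both sides", {
  w <- list(food = matrix(5, 40, 40), denuded = matrix(FALSE, 40, 40),
            predator = matrix(FALSE, 40, 40))
  w$predator[seq_len(16)] <- TRUE
  expect_equal(ground_cover(w), 1)
  # 1584 non-predator patches with 396 denuded leave three quarters covered
  w$denuded[which(!w$predator)[seq_len(396)]] <- TRUE
  expect_equal(ground_cover(w), 0.75)
  w$denuded[!w$predator] <- TRUE
  expect_equal(ground_cover(w), 0)
})

test_that("the shock flips the regime at shock_tick, idempotently, and only then", {
  cfg <- small_config(shock_tick = 50L, recovery_prob = 0)
  log <- run_simulation(cfg, scenario_spec("shock"), seed = 3, n_ticks = 100)
  expect_equal(log$final_state$world$regrowth, cfg$regrowth_shocked)
  # without the shock mechanism the rate never changes
  log2 <- run_simulation(cfg, scenario_spec("genetic"), seed = 3,
                         n_ticks = 100)
  expect_equal(log2$final_state$world$regrowth, cfg$regrowth_normal)
  # applying the shock twice is the same as once
  w <- apply_shock(log2$final_state$world, cfg)
  expect_identical(w, apply_shock(w, cfg))
})

test_that("food stays within [0, F_max] and denuded patches hold zero food", {
  cfg <- small_config(run_length = 400L)
  log <- run_simulation(cfg, scenario_spec("genetic"), seed = 5)
  w <- log$final_state$world
  expect_true(all(w$food >= 0))
  expect_true(all(w$food <= cfg$max_food_per_patch + 1e-9))
  expect_true(all(w$food[w$denuded] == 0))
})
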