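test_that("identical config and seed reproduce a run exactly", {
  cfg <- small_config()
  a <- run_simulation(cfg, scenario_spec("genetic"), seed = 5,
                      record_balance = TRUE)
  b <- run_simulation(cfg, scenario_spec("genetic"), seed = 5,
                      record_balance = TRUE)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$events, b$events)
  expect_identical(a$balance, b$balance)
  expect_identical(a$final_state, b$final_state)
  # a different seed gives a different trajectory
  c2 <- run_simulation(cfg, scenario_spec("genetic"), seed = 6)
  expect_false(identical(a$timeseries, c2$timeseries))
})

test_that("an empty starting population is flagged extinct at tick 0", {
  cfg <- small_config(init_population = 0L, run_length = 10L)
  log <- run_simulation(cfg, scenario_spec("genetic"), seed = 1)
  expect_true(log$extinct)
  expect_equal(log$extinct_tick, 0L)
  expect_true(all(log$timeseries$population == 0))
})

test_that("extinct runs are padded with zero rows to full length", {
  cfg <- small_config(init_population = 2L, run_length = 500L,
                      recovery_prob = 0)
  log <- run_simulation(cfg, scenario_spec("genetic"), seed = 1)
  expect_equal(nrow(log$timeseries), 500)
  if (log$extinct) {
    after <- log$timeseries$tick > log$extinct_tick
    expect_true(all(log$timeseries$population[after] == 0))
    expect_true(all(log$timeseries$wellbeing[after] == 0))
  }
})

test_that("experiments aggregate one run per seed, order-independently", {
  cfg <- small_config()
  sc <- scenario_spec("genetic", n_replicates = 3L, seeds = c(4L, 9L, 2L))
  ex <- run_experiment(cfg, sc)
  expect_length(ex$metrics, 3)
  expect_length(ex$wellbeing, 3)
  expect_true(ex$extinction_count %in% 0:3)
  sc2 <- scenario_spec("genetic", n_replicates = 3L, seeds = c(2L, 4L, 9L))
  ex2 <- run_experiment(cfg, sc2)
  expect_setequal(ex$wellbeing, ex2$wellbeing)
  expect_equal(sort(vapply(ex$metrics, `[[`, numeric(1), "total_deaths")),
               sort(vapply(ex2$metrics, `[[`, numeric(1), "total_deaths")))
})

test_that("the per-tick energy ledger balances on a short run", {
  cfg <- small_config(run_length = 200L)
  log <- run_simulation(cfg, scenario_spec("genetic"), seed = 7,
                        record_balance = TRUE)
  b <- log$balance
  resid <- b$energy_end -
    (b$energy_start + b$intake - b$living_cost - b$birth_cost -
       b$cap_loss - b$death_loss)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("log output files carry the documented shapes", {
  cfg <- small_config()
  log <- run_simulation(cfg, scenario_spec("genetic"), seed = 1)
  expect_named(log$timeseries,
               c("tick", "population", "ground_cover", "mean_patch_food",
                 "mean_energy", "mean_store", "sharers", "sharing_events",
                 "wellbeing", sprintf("f_%.1f", seq(0, 1, 0.1))))
  expect_named(log$events, c("tick", "id", "parent", "event", "cause",
                             "x", "y", "frac"))
  dir <- withr::local_tempdir()
  write_run_log(log, dir)
  expect_true(all(file.exists(file.path(
    dir, c("timeseries.csv", "events.csv", "sharing.csv", "metrics.json")))))
})
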