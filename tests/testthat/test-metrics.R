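fake_log <- function(wellbeing, population = NULL,
                     causes = c(OLD_AGE = 0L, EXHAUSTION = 0L,
                                PREDATION = 0L, BIRTH = 0L)) {
  n <- length(wellbeing)
  if (is.null(population)) population <- rep(3L, n)
  ts <- data.frame(tick = seq_len(n) - 1, population = population,
                   ground_cover = 1, mean_patch_food = 5, mean_energy = 50,
                   mean_store = 10, sharers = 0, sharing_events = 0,
                   wellbeing = wellbeing)
  for (f in sprintf("f_%.1f", seq(0, 1, 0.1))) ts[[f]] <- 0
  ts$f_0.5 <- population
  structure(list(timeseries = ts, cause_counts = causes,
                 n_sharing_events = 0, extinct = FALSE,
                 extinct_tick = -1L, seed = 1L,
                 config = default_config()),
            class = "run_log")
}

test_that("agent-period wellbeing counts healthy agent-ticks", {
  log <- fake_log(rep(3, 10))           # 3 agents healthy for 10 ticks
  expect_equal(wellbeing_agent_periods(log), 30)
  log2 <- fake_log(c(rep(3, 8), 2, 2))  # one agent below threshold twice
  expect_equal(wellbeing_agent_periods(log2), 28)
  # never more than the agent-tick total
  expect_lte(wellbeing_agent_periods(log2),
             sum(log2$timeseries$population))
})

test_that("old-age death fraction is the share of deaths by that cause", {
  log <- fake_log(rep(1, 3), causes = c(OLD_AGE = 13L, EXHAUSTION = 5L,
                                        PREDATION = 2L, BIRTH = 0L))
  expect_equal(old_age_death_fraction(log), 0.65)
  log2 <- fake_log(rep(1, 3), causes = c(OLD_AGE = 7L, EXHAUSTION = 0L,
                                         PREDATION = 0L, BIRTH = 0L))
  expect_equal(old_age_death_fraction(log2), 1)
  log3 <- fake_log(rep(1, 3))
  expect_error(old_age_death_fraction(log3), "no deaths")
})

test_that("experiment spread reports extreme deviations from the mean", {
  expect_equal(unname(experiment_spread(c(98, 100, 102))), c(2, 2))
  expect_equal(unname(experiment_spread(42)), c(0, 0))
  expect_equal(unname(experiment_spread(rep(7, 5))), c(0, 0))
  expect_error(experiment_spread(c(-1, 1)), "mean is zero")
  expect_error(experiment_spread(numeric(0)), "no values")
})

test_that("metrics recomputed from a written-and-reloaded log are identical", {
  cfg <- small_config(innovation_prob = 0.1)
  log <- run_simulation(cfg, scenario_spec("sharing"), seed = 2)
  dir <- withr::local_tempdir()
  write_run_log(log, dir)
  back <- read_run_log(dir, cfg)
  expect_identical(wellbeing_agent_periods(back, cfg),
                   wellbeing_agent_periods(log, cfg))
  expect_equal(as.integer(back$cause_counts), as.integer(log$cause_counts))
  expect_identical(back$n_sharing_events, log$n_sharing_events)
  m1 <- run_metrics(log, cfg)
  m2 <- run_metrics(back, cfg)
  expect_identical(m1$wellbeing_agent_periods, m2$wellbeing_agent_periods)
  expect_equal(m1$old_age_death_fraction, m2$old_age_death_fraction)
  expect_equal(m1$steady_frac0_share, m2$steady_frac0_share)
})

test_that("run metrics agree with the raw event stream", {
  cfg <- small_config()
  log <- run_simulation(cfg, scenario_spec("genetic"), seed = 3)
  m <- run_metrics(log, cfg)
  deaths <- log$events[log$events$event == "DEATH", ]
  expect_equal(m$total_deaths, nrow(deaths))
  expect_equal(unname(m$cause_counts["OLD_AGE"]),
               sum(deaths$cause == "OLD_AGE"))
  expect_equal(m$final_population,
               utils::tail(log$timeseries$population, 1))
  expect_equal(sum(m$final_fraction_histogram), m$final_population)
})
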