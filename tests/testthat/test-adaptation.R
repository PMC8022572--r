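test_that("the vicinity ledger records nearby events and forgets old ones", {
  cfg <- classic_config()  # vicinity radius 2, window 20
  led <- new_ledger()
  ev <- data.frame(x = c(5, 10), y = c(5, 5),
                   event = c("BIRTH", "DEATH"), stringsAsFactors = FALSE)
  led <- record_local_events(led, ev, position = c(4, 5), tick = 10, config = cfg)
  expect_equal(nrow(led), 1)           # the birth 1 patch away, not the death 6 away
  expect_equal(led$event, "BIRTH")

  # torus wrap: an event across the seam is near
  evw <- data.frame(x = cfg$grid_width, y = 1, event = "DEATH",
                    stringsAsFactors = FALSE)
  led2 <- record_local_events(new_ledger(), evw, position = c(1, 1),
                              tick = 1, config = cfg)
  expect_equal(nrow(led2), 1)

  # entries age out of the window
  led3 <- record_local_events(led, ev[0, ], position = c(4, 5),
                              tick = 10 + cfg$ledger_window, config = cfg)
  expect_equal(nrow(led3), 0)
})

test_that("skew moves the fraction by one step against the excess", {
  cfg <- classic_config()  # threshold 3
  expect_equal(adapt_fraction(0.5, skew = 4, cfg), 0.4)
  expect_equal(adapt_fraction(0.5, skew = -4, cfg), 0.6)
  expect_equal(adapt_fraction(0.5, skew = 0, cfg), 0.5)
  expect_equal(adapt_fraction(0.5, skew = 3, cfg), 0.5)   # at threshold: no move
  expect_equal(adapt_fraction(0.0, skew = 4, cfg), 0.0)   # boundary clamp
  expect_equal(adapt_fraction(1.0, skew = -4, cfg), 1.0)
})

test_that("ledger skew is births minus deaths", {
  led <- data.frame(tick = c(1, 1, 2, 3),
                    event = c("BIRTH", "BIRTH", "DEATH", "BIRTH"),
                    stringsAsFactors = FALSE)
  expect_equal(ledger_skew(led), 2)
  expect_equal(ledger_skew(new_ledger()), 0)
})

test_that("an isolated agent's fraction never changes", {
  cfg <- classic_config(grid_width = 1L, grid_height = 1L,
                        n_predator_patches = 0L, recovery_prob = 0,
                        repro_age_min = 900L, repro_age_max = 1000L,
                        old_age_threshold = 2000L, innovation_prob = 0)
  st <- list(world = one_patch_world(food = 5),
             agents = list(id = 1L, x = 1L, y = 1L, frac = 0.5,
                           energy = 80, store = 40, age = 0L, sharer = FALSE,
                           ledger_births = matrix(0L, 1, cfg$ledger_window),
                           ledger_deaths = matrix(0L, 1, cfg$ledger_window)))
  log <- run_simulation(cfg, scenario_spec("adaptive"), seed = 2,
                        n_ticks = 100, init_state = st)
  expect_equal(log$final_state$agents$frac, 0.5)
})

test_that("adaptive runs keep every fraction on the 0.1 grid in [0, 1]", {
  cfg <- small_config(run_length = 200L)
  log <- run_simulation(cfg, scenario_spec("adaptive"), seed = 8)
  fr <- c(log$final_state$agents$frac, log$events$frac)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(abs(fr * 10 - round(fr * 10)) < 1e-9))
  # the fraction histogram always sums to the population
  hist_cols <- grep("^f_", names(log$timeseries))
  expect_equal(rowSums(log$timeseries[, hist_cols]),
               log$timeseries$population)
})
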