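TS_COLS <- c("tick", "population", "ground_cover", "mean_patch_food",
             "mean_energy", "mean_store", "sharers", "sharing_events",
             "wellbeing", sprintf("f_%.1f", seq(0, 1, by = 0.1)))

BAL_COLS <- c("energy_start", "energy_end", "intake", "living_cost",
              "birth_cost", "cap_loss", "death_loss")

CAUSE_LEVELS <- c("OLD_AGE", "EXHAUSTION", "PREDATION", "BIRTH")

#' Run one simulation
#'
#' Executes `config$run_length` ticks (or `n_ticks` if given), or stops early
#' at extinction; extinct runs are padded with zero rows so time series stay
#' rectangular. A single RNG stream seeded with `seed` drives every
#' stochastic element (initialisation, movement, mutation, mortality,
#' recovery, innovation, and the per-tick shuffle of agent order), so a run
#' is fully reproducible from `(config, scenario, seed)`.
#'
#' @param config A `sim_config`.
#' @param scenario A `scenario_spec`.
#' @param seed Integer RNG seed for this run.
#' @param n_ticks Number of ticks (defaults to `config$run_length`).
#' @param record_events Keep the full birth/death event stream (needed for
#'   event-level analysis; per-cause totals are always kept).
#' @param record_balance Keep the per-tick energy ledger components used by
#'   the conservation check.
#' @param init_state Optionally a prepared `sim_state` to start from instead
#'   of a fresh initialisation (used by the fixture catalogue).
#' @return A `run_log` with elements `timeseries` (one row per tick),
#'   `events`, `sharing`, `cause_counts`, `balance`, `final_state`,
#'   `extinct`, `extinct_tick`, `innovation_tick`, `seed`, `scenario`, and
#'   `config`.
#' @examples
#' cfg <- config_override(default_config(), list(run_length = 200))
#' log <- run_simulation(cfg, scenario_spec("genetic"), seed = 1)
#' tail(log$timeseries$population, 1)
#' @export
run_simulation <- function(config, scenario = scenario_spec("genetic"),
                           seed = 1L, n_ticks = NULL,
                           record_events = TRUE, record_balance = FALSE,
                           init_state = NULL) {
  config <- validate_config(config)
  if (is.null(n_ticks)) n_ticks <- config$run_length
  set.seed(seed)
  res <- sim_run_cpp(unclass(config), scenario_flags(scenario), init_state,
                     as.integer(n_ticks), record_events, record_balance)
  ts <- as.data.frame(res$timeseries)
  names(ts) <- TS_COLS
  ev <- as.data.frame(res$events)
  ev$event <- c("BIRTH", "DEATH")[ev$type]
  cause_chr <- rep(NA_character_, nrow(ev))
  is_death <- ev$type == 2
  cause_chr[is_death] <- CAUSE_LEVELS[ev$cause[is_death]]
  ev$cause <- cause_chr
  ev$type <- NULL
  ev <- ev[, c("tick", "id", "parent", "event", "cause", "x", "y", "frac")]
  sh <- as.data.frame(res$sharing)
  bal <- NULL
  if (record_balance) {
    bal <- as.data.frame(res$balance)
    names(bal) <- BAL_COLS
  }
  structure(
    list(timeseries = ts, events = ev, sharing = sh,
         cause_counts = res$cause_counts,
         n_sharing_events = res$n_sharing_events,
         balance = bal,
         final_state = list(world = res$world, agents = res$agents),
         extinct = res$extinct, extinct_tick = res$extinct_tick,
         innovation_tick = res$innovation_tick,
         seed = seed, scenario = scenario, config = config),
    class = "run_log")
}

#' @export
print.run_log <- function(x, ...) {
  n <- nrow(x$timeseries)
  cat("<run_log> scenario ", x$scenario$name, ", seed ", x$seed, ", ",
      n, " ticks\n", sep = "")
  if (x$extinct) cat("  extinct at tick", x$extinct_tick, "\n")
  else cat("  final population", utils::tail(x$timeseries$population, 1), "\n")
  invisible(x)
}

#' Run a replicate experiment
#'
#' Runs the scenario once per seed in `scenario$seeds`, each run independent
#' and reproducible in isolation, then aggregates per-run summaries: the
#' across-run mean of the agent-period wellbeing measure, its maximum and
#' minimum relative deviations, the pooled old-age death fraction, and the
#' extinction count.
#'
#' @param config A `sim_config`.
#' @param scenario A `scenario_spec` carrying the seed list.
#' @param keep_logs Keep the full per-run logs (memory heavy for long runs).
#' @param record_events Forwarded to [run_simulation()].
#' @return An `experiment_result` with `metrics` (list of per-run
#'   `run_metrics`), `wellbeing` (per-run counts), `spread`
#'   (max/min relative deviation in percent), `extinction_count`,
#'   `pooled_old_age_fraction`, and optionally `logs`.
#' @export
run_experiment <- function(config, scenario, keep_logs = FALSE,
                           record_events = FALSE) {
  config <- validate_config(config)
  metrics <- vector("list", scenario$n_replicates)
  logs <- if (keep_logs) vector("list", scenario$n_replicates) else NULL
  for (i in seq_along(scenario$seeds)) {
    log <- run_simulation(config, scenario, seed = scenario$seeds[i],
                          record_events = record_events)
    metrics[[i]] <- run_metrics(log, config)
    if (keep_logs) logs[[i]] <- log
  }
  wb <- vapply(metrics, `[[`, numeric(1), "wellbeing_agent_periods")
  deaths <- Reduce(`+`, lapply(metrics, `[[`, "cause_counts"))
  structure(
    list(metrics = metrics, wellbeing = wb,
         spread = experiment_spread(wb),
         extinction_count = sum(vapply(metrics, `[[`, logical(1), "extinct")),
         pooled_cause_counts = deaths,
         pooled_old_age_fraction =
           unname(deaths["OLD_AGE"] / sum(deaths)),
         scenario = scenario, config = config,
         logs = logs),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> scenario ", x$scenario$name, ", ",
      x$scenario$n_replicates, " replicates\n", sep = "")
  cat(sprintf("  wellbeing mean %.0f (max +%.2f%%, min -%.2f%%)\n",
              mean(x$wellbeing), x$spread[1], x$spread[2]))
  cat(sprintf("  old-age death fraction %.3f, extinctions %d\n",
              x$pooled_old_age_fraction, x$extinction_count))
  invisible(x)
}

#' Write a run log to a directory
#'
#' Writes `timeseries.csv`, `events.csv`, `sharing.csv`, and `metrics.json`.
#'
#' @param log A `run_log`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_log <- function(log, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(log$timeseries, file.path(dir, "timeseries.csv"),
                   row.names = FALSE)
  utils::write.csv(log$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(log$sharing, file.path(dir, "sharing.csv"),
                   row.names = FALSE)
  m <- unclass(run_metrics(log, log$config))
  m$cause_counts <- as.list(m$cause_counts)
  m$final_fraction_histogram <- as.list(m$final_fraction_histogram)
  jsonlite::write_json(m, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back a run log written by [write_run_log()]
#'
#' Restores the tabular parts of a log (time series, events, sharing) so
#' that metrics can be recomputed from disk.
#'
#' @param dir Directory written by [write_run_log()].
#' @param config The `sim_config` of the run.
#' @return A list with `timeseries`, `events`, `sharing`, and
#'   `cause_counts`, usable by the metric functions.
#' @export
read_run_log <- function(dir, config) {
  ts <- utils::read.csv(file.path(dir, "timeseries.csv"),
                        check.names = FALSE)
  ts[] <- lapply(ts, as.numeric)  # the engine logs doubles throughout
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        stringsAsFactors = FALSE)
  sh <- utils::read.csv(file.path(dir, "sharing.csv"))
  deaths <- ev[ev$event == "DEATH", ]
  cc <- vapply(CAUSE_LEVELS, function(k) sum(deaths$cause == k), integer(1))
  structure(list(timeseries = ts, events = ev, sharing = sh,
                 cause_counts = cc, n_sharing_events = nrow(sh),
                 config = config),
            class = "run_log")
}
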