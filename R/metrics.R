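#' Agent-period wellbeing
#'
#' The first outcome measure: the count over all ticks of living agents that
#' were not just about to starve. "About to starve" is operationalised as an
#' end-of-tick energy below `wellbeing_energy_multiple * living_cost`
#' together with an empty store, i.e. the agent would die within about two
#' ticks without finding food. More agents alive means more wellbeing,
#' subject to those agents not being in a bad state; extinct runs contribute
#' their truncated count.
#'
#' @param log A `run_log`.
#' @param config A `sim_config` (the multiple used is the one the run was
#'   logged with; kept as an argument for sensitivity analysis on reloaded
#'   logs).
#' @return The total number of qualifying agent-periods.
#' @export
wellbeing_agent_periods <- function(log, config = log$config) {
  sum(log$timeseries$wellbeing)
}

#' Fraction of deaths due to old age
#'
#' The second outcome measure: of all deaths in the run, the share whose
#' cause was old age. Agents cannot reproduce over their whole lives, so
#' reaching old age reflects a notion of quality of life beyond reproductive
#' output.
#'
#' @param log A `run_log` (or anything with a `cause_counts` vector).
#' @return A fraction in \[0, 1\].
#' @export
old_age_death_fraction <- function(log) {
  cc <- log$cause_counts
  total <- sum(cc)
  if (total == 0) stop("old_age_death_fraction is undefined: no deaths")
  unname(cc["OLD_AGE"] / total)
}

#' Across-run spread of an outcome measure
#'
#' Returns how far the maximum and minimum run values deviate from the
#' across-run mean, as percentages of the mean: `(max - mean)/mean` and
#' `(mean - min)/mean`.
#'
#' @param values Per-run values of the measure.
#' @return A length-2 named numeric vector, in percent.
#' @examples
#' experiment_spread(c(98, 100, 102))  # 2% above, 2% below
#' @export
experiment_spread <- function(values) {
  if (length(values) == 0) stop("no values")
  m <- mean(values)
  if (m == 0) stop("experiment_spread is undefined: mean is zero")
  c(max_above = 100 * (max(values) - m) / m,
    min_below = 100 * (m - min(values)) / m)
}

#' Per-run summary metrics
#'
#' Condenses a `run_log` into the quantities the analyses use: the two
#' wellbeing measures, extinction status, mean ground cover before and after
#' the shock tick, the final foraging-gene histogram, sharing totals, and
#' steady-state summaries over the final window of the run.
#'
#' @param log A `run_log`.
#' @param config A `sim_config`.
#' @param steady_window Number of final ticks treated as steady state for
#'   the time-averaged population and zero-fraction share (default 5000,
#'   truncated to the run length).
#' @return A list of class `run_metrics`.
#' @export
run_metrics <- function(log, config = log$config, steady_window = 5000L) {
  ts <- log$timeseries
  n <- nrow(ts)
  extinct <- if (!is.null(log$extinct)) log$extinct
             else utils::tail(ts$population, 1) == 0
  alive_rows <- ts$population > 0

  total_deaths <- sum(log$cause_counts)
  oa <- if (total_deaths > 0) old_age_death_fraction(log) else NA_real_

  shock_tick <- config$shock_tick
  pre <- ts$tick < shock_tick & alive_rows
  post <- ts$tick >= shock_tick & alive_rows
  gc_pre <- if (any(pre)) mean(ts$ground_cover[pre]) else NA_real_
  gc_post <- if (any(post)) mean(ts$ground_cover[post]) else NA_real_

  w <- min(steady_window, n)
  tail_rows <- ts[seq.int(n - w + 1, n), , drop = FALSE]
  tail_rows <- tail_rows[tail_rows$population > 0, , drop = FALSE]
  frac0_share <- if (nrow(tail_rows) > 0)
    mean(tail_rows$f_0.0 / tail_rows$population) else NA_real_
  steady_pop <- if (nrow(tail_rows) > 0)
    mean(tail_rows$population) else 0

  final_pop <- utils::tail(ts$population, 1)
  hist_cols <- grep("^f_", names(ts))
  final_hist <- as.numeric(utils::tail(ts[, hist_cols], 1))
  names(final_hist) <- names(ts)[hist_cols]

  structure(list(
    wellbeing_agent_periods = wellbeing_agent_periods(log, config),
    old_age_death_fraction = oa,
    cause_counts = log$cause_counts,
    total_deaths = total_deaths,
    extinct = extinct,
    extinct_tick = if (extinct) log$extinct_tick else NA_integer_,
    mean_ground_cover_pre_shock = gc_pre,
    mean_ground_cover_post_shock = gc_post,
    final_population = final_pop,
    steady_population = steady_pop,
    steady_frac0_share = frac0_share,
    final_fraction_histogram = final_hist,
    total_sharing_events = log$n_sharing_events,
    sharer_fraction_end = if (final_pop > 0)
      utils::tail(log$timeseries$sharers, 1) / final_pop else NA_real_,
    seed = log$seed
  ), class = "run_metrics")
}

#' @export
print.run_metrics <- function(x, ...) {
  cat("<run_metrics>\n")
  cat(sprintf("  wellbeing agent-periods  %d\n",
              as.integer(x$wellbeing_agent_periods)))
  cat(sprintf("  old-age death fraction   %.3f (of %d deaths)\n",
              x$old_age_death_fraction, x$total_deaths))
  cat(sprintf("  steady population        %.1f%s\n", x$steady_population,
              if (x$extinct) sprintf("  [extinct at %d]", x$extinct_tick)
              else ""))
  invisible(x)
}
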