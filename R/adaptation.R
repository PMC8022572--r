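#' Create an empty vicinity ledger
#'
#' The ledger is each agent's forgetting record of births and deaths that
#' happened within `vicinity_radius` (Chebyshev distance on the torus) of its
#' position, over the last `ledger_window` ticks. Its net skew
#' (births minus deaths) drives within-lifetime foraging adjustment in the
#' adaptive scenario.
#'
#' @return A zero-row data frame with columns `tick` and `event`.
#' @export
new_ledger <- function() {
  data.frame(tick = integer(0),
             event = character(0), stringsAsFactors = FALSE)
}

torus_chebyshev <- function(x1, y1, x2, y2, w, h) {
  dx <- abs(x1 - x2); dx <- pmin(dx, w - dx)
  dy <- abs(y1 - y2); dy <- pmin(dy, h - dy)
  pmax(dx, dy)
}

#' Record this tick's local birth/death events in an agent's ledger
#'
#' Events within `vicinity_radius` of `position` are appended with the
#' current tick; entries older than `ledger_window` ticks are forgotten.
#'
#' @param ledger A ledger data frame from [new_ledger()].
#' @param events A data frame with columns `x`, `y`, `event` (`"BIRTH"` or
#'   `"DEATH"`) for this tick.
#' @param position Length-2 integer vector, the agent's position.
#' @param tick Current tick.
#' @param config A `sim_config` (vicinity radius, window, grid size).
#' @return The updated ledger.
#' @export
record_local_events <- function(ledger, events, position, tick, config) {
  if (nrow(events) > 0) {
    d <- torus_chebyshev(events$x, events$y, position[1], position[2],
                         config$grid_width, config$grid_height)
    keep <- events[d <= config$vicinity_radius, c("x", "y", "event")]
    if (nrow(keep) > 0) {
      ledger <- rbind(ledger,
                      data.frame(tick = tick, event = keep$event,
                                 stringsAsFactors = FALSE))
    }
  }
  ledger[ledger$tick > tick - config$ledger_window, , drop = FALSE]
}

#' Net skew of a ledger
#'
#' @param ledger A ledger data frame.
#' @return Number of recorded births minus number of recorded deaths.
#' @export
ledger_skew <- function(ledger) {
  sum(ledger$event == "BIRTH") - sum(ledger$event == "DEATH")
}

#' Adjust the foraging fraction from the ledger skew
#'
#' If the skew exceeds `ledger_skew_threshold` (an excess of births) the
#' agent cuts its foraging fraction by 0.1; if it falls below the negative
#' threshold (an excess of deaths) the agent raises it by 0.1. The result is
#' clamped to the 0.1 grid in \[0, 1\]; at most one step per tick.
#'
#' @param frac Current foraging fraction.
#' @param skew Ledger skew (births minus deaths).
#' @param config A `sim_config`.
#' @return The adjusted fraction.
#' @examples
#' adapt_fraction(0.5, skew = 4, default_config())   # 0.4
#' adapt_fraction(0.5, skew = -4, default_config())  # 0.6
#' @export
adapt_fraction <- function(frac, skew, config) {
  if (skew > config$ledger_skew_threshold) frac <- frac - 0.1
  else if (skew < -config$ledger_skew_threshold) frac <- frac + 0.1
  round(min(1, max(0, frac)) * 10) / 10
}
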