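#' Innovation of the sharing practice
#'
#' At the start of a sharing-enabled run nobody shares. Once per tick, if no
#' living agent carries the practice, it can dawn on one uniformly chosen
#' agent with probability `innovation_prob`. While at least one sharer is
#' alive no innovation draw occurs.
#'
#' @param agents A list of per-agent vectors (as in `sim_state$agents`),
#'   needing at least `sharer`.
#' @param config A `sim_config`.
#' @return The updated agents list.
#' @export
innovate_sharing <- function(agents, config) {
  n <- length(agents$sharer)
  if (n == 0 || any(agents$sharer)) return(agents)
  if (stats::runif(1) < config$innovation_prob) {
    agents$sharer[sample.int(n, 1)] <- TRUE
  }
  agents
}

#' Food sharing with a near-exhausted neighbour
#'
#' A sharer whose store holds at least `share_donor_store_fraction` of the
#' storage capacity donates to a neighbour (within `share_radius`, Chebyshev
#' distance on the torus) whose energy is below
#' `share_recipient_energy_multiple * living_cost` and whose store is empty.
#' The neediest (lowest energy, ties by lowest id) qualifying neighbour
#' receives `min(share_amount, donor store)` food straight into its energy
#' (capped at the energy capacity; overflow is lost and reported). Kinship is
#' never consulted; at most one transfer per donor per tick.
#'
#' @param donor A `sim_agent` with `sharer = TRUE`.
#' @param neighbors A list of `sim_agent`s within the sharing radius.
#' @param config A `sim_config`.
#' @return A list with the updated `donor`, updated `neighbors`, and `event`
#'   (a list with donor/recipient ids and `amount`, or `NULL` if no transfer
#'   happened).
#' @export
share_food <- function(donor, neighbors, config) {
  no_event <- list(donor = donor, neighbors = neighbors, event = NULL)
  if (!isTRUE(donor$sharer)) return(no_event)
  if (donor$store < config$share_donor_store_fraction *
        config$storage_capacity) return(no_event)
  thr <- config$share_recipient_energy_multiple * config$living_cost
  needy <- which(vapply(neighbors, function(b)
    b$energy < thr && b$store <= 1e-9 && b$id != donor$id, logical(1)))
  if (length(needy) == 0) return(no_event)
  en <- vapply(neighbors[needy], `[[`, numeric(1), "energy")
  ids <- vapply(neighbors[needy], `[[`, integer(1), "id")
  pick <- needy[order(en, ids)[1]]
  amount <- min(config$share_amount, donor$store)
  if (amount <= 0) return(no_event)
  donor$store <- donor$store - amount
  gain <- amount * config$food_to_energy
  room <- config$energy_capacity - neighbors[[pick]]$energy
  overflow <- max(0, gain - room)
  neighbors[[pick]]$energy <- min(config$energy_capacity,
                                  neighbors[[pick]]$energy + gain)
  list(donor = donor, neighbors = neighbors,
       event = list(donor = donor$id, recipient = neighbors[[pick]]$id,
                    amount = amount, overflow = overflow))
}

#' Vertical transmission of the sharing practice
#'
#' Offspring copy the parent's sharer flag exactly; there is no horizontal
#' imitation and no cultural mutation other than innovation-from-zero.
#'
#' @param parent,offspring `sim_agent`s.
#' @return The offspring with the inherited flag.
#' @export
transmit_sharing <- function(parent, offspring) {
  offspring$sharer <- isTRUE(parent$sharer)
  offspring
}
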