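#' Scenario specification
#'
#' The model is studied in four named variants. `"genetic"` is the baseline:
#' foraging genes evolve by mutation and selection only. `"shock"` adds a
#' permanent mid-run drop of patch regrowth from the normal to the shocked
#' rate. `"sharing"` adds the socially innovated, vertically transmitted
#' food-sharing practice to the baseline (no shock), matching the paired
#' sharing-versus-no-sharing comparison the measures are designed for.
#' `"adaptive"` replaces fixed-for-life genes with within-lifetime adjustment
#' of the foraging fraction driven by the vicinity birth/death ledger
#' (offspring still inherit the parent's current fraction through the
#' mutation kernel). The individual mechanism switches can also be set
#' directly for custom combinations.
#'
#' @param name One of `"genetic"`, `"shock"`, `"sharing"`, `"adaptive"`, or
#'   `"custom"` (then set the flags yourself).
#' @param shock,sharing,adaptive Mechanism switches; defaults follow `name`.
#' @param predators_enabled If `FALSE` the world has no predator patches
#'   (the population regulator is removed; the baseline then booms and
#'   collapses).
#' @param n_replicates Number of replicate runs in an experiment.
#' @param seeds Integer seed vector, one per replicate (default
#'   `1:n_replicates`).
#' @return A list of class `scenario_spec`.
#' @examples
#' scenario_spec("shock")
#' scenario_spec("genetic", predators_enabled = FALSE)
#' @export
scenario_spec <- function(name = c("genetic", "shock", "sharing", "adaptive",
                                   "custom"),
                          shock = NULL, sharing = NULL, adaptive = NULL,
                          predators_enabled = TRUE,
                          n_replicates = 10L, seeds = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    genetic  = list(shock = FALSE, sharing = FALSE, adaptive = FALSE),
    shock    = list(shock = TRUE,  sharing = FALSE, adaptive = FALSE),
    sharing  = list(shock = FALSE, sharing = TRUE,  adaptive = FALSE),
    adaptive = list(shock = FALSE, sharing = FALSE, adaptive = TRUE),
    custom   = list(shock = FALSE, sharing = FALSE, adaptive = FALSE)
  )
  if (is.null(shock)) shock <- defaults$shock
  if (is.null(sharing)) sharing <- defaults$sharing
  if (is.null(adaptive)) adaptive <- defaults$adaptive
  if (is.null(seeds)) seeds <- seq_len(n_replicates)
  n_replicates <- as.integer(n_replicates)
  if (length(seeds) != n_replicates)
    stop("seed list length (", length(seeds),
         ") must equal n_replicates (", n_replicates, ")")
  for (f in c(shock, sharing, adaptive, predators_enabled))
    stopifnot(is.logical(f), length(f) == 1, !is.na(f))
  structure(
    list(name = name, shock = shock, sharing = sharing, adaptive = adaptive,
         predators_enabled = predators_enabled,
         n_replicates = n_replicates, seeds = as.integer(seeds)),
    class = "scenario_spec"
  )
}

scenario_flags <- function(scenario) {
  list(shock = scenario$shock, sharing = scenario$sharing,
       adaptive = scenario$adaptive, predators = scenario$predators_enabled)
}

#' @export
print.scenario_spec <- function(x, ...) {
  mech <- c("genetic evolution",
            if (x$shock) "regrowth shock",
            if (x$sharing) "sharing practice",
            if (x$adaptive) "adaptive foraging")
  cat("<scenario_spec> ", x$name, "\n",
      "  mechanisms: ", paste(mech, collapse = " + "), "\n",
      "  predators:  ", x$predators_enabled, "\n",
      "  replicates: ", x$n_replicates,
      " (seeds ", paste(range(x$seeds), collapse = ".."), ")\n", sep = "")
  invisible(x)
}
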