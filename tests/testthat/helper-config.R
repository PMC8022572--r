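# Small worlds and classic physiology used throughout the unit tests.
# `classic_config` pins the unit-scale economy (living cost 1, refill at 10,
# reproduction at 0.6*E_max costing 15+25) so hand-worked expected values in
# the tests stay simple integers whatever the shipped calibration is.

classic_config <- function(...) {
  config_override(default_config(), utils::modifyList(
    list(living_cost = 1, refill_threshold = 10,
         repro_energy_fraction = 0.6, birth_cost = 15, birth_transfer = 25,
         share_recipient_energy_multiple = 2, share_radius = 1L,
         ledger_window = 20L, ledger_skew_threshold = 3L,
         vicinity_radius = 2L),
    list(...)))
}

small_config <- function(...) {
  config_override(default_config(), utils::modifyList(
    list(grid_width = 12L, grid_height = 12L, n_predator_patches = 2L,
         init_population = 30L, run_length = 300L),
    list(...)))
}

# one-patch world builder mirroring the fixture module's internals
one_patch_world <- function(food = 0, denuded = FALSE, predator = FALSE,
                            regrowth = 1, tick = 0L) {
  list(food = matrix(as.numeric(food), 1, 1),
       denuded = matrix(denuded, 1, 1),
       predator = matrix(predator, 1, 1),
       regrowth = regrowth, tick = as.integer(tick))
}
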