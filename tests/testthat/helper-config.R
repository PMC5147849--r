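# Small configurations for fast unit tests, and a cache of the full-size
# replicate sets shared between the regime/property tests so each is
# simulated only once per test run.

small_config <- function(...) {
  args <- list(
    grid_width = 9, grid_height = 9, n_cells = 15,
    site_mean = 3, site_sd = 1,
    initial_release = c(LA = 30L, MA = 30L, HA = 30L),
    n_steps = 30, n_replicates = 2, seed = 101
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# A state with one factor of each class bound to one co-located cell, on a
# single patch with a fixed heparinase level. Used by the cleavage tests.
bound_triplet_state <- function(h, cleaved_fate = "degrade") {
  cfg <- simulation_config(
    grid_width = 1, grid_height = 1, n_cells = 1,
    site_mean = 3, site_sd = 0,
    attach_prob = 1,
    initial_release = c(1L, 1L, 1L),
    heparinase_init = h, flux_prob = 0,
    cleaved_fate = cleaved_fate,
    n_steps = 1, n_replicates = 1, seed = 5
  )
  st <- init_simulation(cfg, 0)
  for (id in 1:3) st <- attempt_binding(st, id)
  stopifnot(all(st$factors$state == 2L))
  st
}

.hs_run_cache <- new.env(parent = emptyenv())

# Ten default-size replicates of a named preset, computed once per session.
cached_replicates <- function(name) {
  if (!exists(name, envir = .hs_run_cache)) {
    cfg <- if (name == "wound_healing") simulation_config() else apply_scenario(name)
    assign(name, run_replicates(cfg), envir = .hs_run_cache)
  }
  get(name, envir = .hs_run_cache)
}
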