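# The per-step scheduler and the replicate runner.

#' Advance the simulation by one scheduler step
#'
#' Executes the model's six-event sequence exactly in order:
#' \enumerate{
#'   \item inflow release (`inflow_per_step`; tumor mode only),
#'   \item every free factor takes one random-walk step,
#'   \item every free factor makes one binding attempt (factors are
#'     processed in a freshly shuffled uniform random order, so competition
#'     for scarce sites carries no creation-order bias),
#'   \item every factor that entered the step bound is checked for cleavage
#'     against its patch's current heparinase (an attachment formed during
#'     this step is first evaluated on the next step),
#'   \item heparinase flux on every patch,
#' }
#' and finally increments the step counter. Factors released by the inflow
#' event move and may bind within the same step.
#'
#' @param state An `hs_state`.
#' @return The state after one step.
#' @seealso [run_simulation()] for full runs.
#' @export
simulate_step <- function(state) {
  cfg <- state$config

  # (1) inflow release (all-zero inflow = wound-healing mode: no-op)
  if (any(cfg$inflow_per_step > 0L))
    state <- release_cytokines(state, cfg$inflow_per_step)

  # factors bound before this step's binding phase: the cleavage cohort
  prev_bound <- which(state$factors$state == FS_BOUND)

  # (2) + (3) movement, then binding attempts, in one shuffled order
  free_ids <- which(state$factors$state == FS_FREE)
  if (length(free_ids) > 1L) free_ids <- free_ids[sample.int(length(free_ids))]
  state <- move_phase(state, free_ids)
  state <- bind_phase(state, free_ids)

  # (4) cleavage of previously bound factors
  if (length(prev_bound)) state <- cleave_ids(state, prev_bound)

  # (5) heparinase flux
  state <- update_heparinase(state)

  state$t <- state$t + 1L
  state
}

series_matrix <- function(n_steps) {
  matrix(0L, nrow = n_steps + 1L, ncol = 3L,
         dimnames = list(step = 0:n_steps, class = HS_CLASSES))
}


#' Run one full replicate
#'
#' Initializes a state from `(config, replicate_index)` and advances it
#' `n_steps` scheduler steps, recording per-class bound, free, cleaved and
#' cumulative-released counts at every step including t = 0. Deterministic
#' given `(config, replicate_index)`.
#'
#' @inheritParams init_simulation
#' @param check Verify the state invariants (site-occupancy conservation,
#'   mass balance, heparinase bounds; see [check_invariants()]) after every
#'   step. Costs a few percent of runtime.
#' @return An object of class `hs_run` with matrices `bound`, `free`,
#'   `cleaved`, `released` of dimension `(n_steps + 1) x 3` (rows t =
#'   0..n_steps; columns LA, MA, HA), the configuration, the replicate
#'   index and a `final_state` summary.
#' @examples
#' cfg <- simulation_config(grid_width = 11, grid_height = 11, n_cells = 20,
#'                          initial_release = 30, n_steps = 20)
#' r <- run_simulation(cfg, 0)
#' tail(r$bound)
#' @export
run_simulation <- function(config, replicate_index = 0L, check = FALSE) {
  validate_config(config)
  state <- init_simulation(config, replicate_index)
  # Recording matrices stay local so row writes do not copy them.
  bound <- series_matrix(config$n_steps)
  free <- series_matrix(config$n_steps)
  cleaved <- series_matrix(config$n_steps)
  released <- series_matrix(config$n_steps)
  f <- state$factors
  bound[1L, ] <- class_counts(f, FS_BOUND)
  free[1L, ] <- class_counts(f, FS_FREE)
  cleaved[1L, ] <- class_counts(f, FS_CLEAVED)
  released[1L, ] <- unname(state$released)
  if (config$n_steps > 0L) for (s in seq_len(config$n_steps)) {
    state <- simulate_step(state)
    if (check) check_invariants(state)
    f <- state$factors
    row <- s + 1L
    bound[row, ] <- class_counts(f, FS_BOUND)
    free[row, ] <- class_counts(f, FS_FREE)
    cleaved[row, ] <- class_counts(f, FS_CLEAVED)
    released[row, ] <- unname(state$released)
  }
  run <- list(
    config = config,
    replicate_index = as.integer(replicate_index),
    bound = bound,
    free = free,
    cleaved = cleaved,
    released = released
  )
  run$final_state <- list(
    bound = class_counts(state$factors, FS_BOUND),
    free = class_counts(state$factors, FS_FREE),
    cleaved = class_counts(state$factors, FS_CLEAVED),
    released = unname(state$released),
    heparinase_mean = mean(state$heparinase)
  )
  class(run) <- "hs_run"
  run
}

#' Run all replicates and average their bound time series
#'
#' Runs replicates `0 .. n_replicates - 1`, each with its own random stream
#' derived from `seed + replicate_index`, and computes the pointwise
#' arithmetic mean bound and free series across replicates.
#'
#' @inheritParams run_simulation
#' @return An object of class `hs_replicates`: `runs` (list of `hs_run`),
#'   `mean_bound` and `mean_free` (numeric `(n_steps + 1) x 3` matrices),
#'   and the configuration.
#' @examples
#' cfg <- simulation_config(grid_width = 11, grid_height = 11, n_cells = 20,
#'                          initial_release = 30, n_steps = 20,
#'                          n_replicates = 3)
#' rr <- run_replicates(cfg)
#' str(rr$mean_bound)
#' @export
run_replicates <- function(config, check = FALSE) {
  validate_config(config)
  runs <- lapply(seq_len(config$n_replicates) - 1L,
                 function(r) run_simulation(config, r, check = check))
  out <- list(
    config = config,
    runs = runs,
    mean_bound = average_replicates(lapply(runs, `[[`, "bound")),
    mean_free = average_replicates(lapply(runs, `[[`, "free"))
  )
  class(out) <- "hs_replicates"
  out
}

#' @export
print.hs_run <- function(x, ...) {
  cat(sprintf("<hs_run> replicate %d: %d steps\n", x$replicate_index, x$config$n_steps))
  cat("  final bound  LA/MA/HA:", x$final_state$bound, "\n")
  cat("  final free   LA/MA/HA:", x$final_state$free, "\n")
  cat("  final cleaved LA/MA/HA:", x$final_state$cleaved, "\n")
  invisible(x)
}

#' @export
print.hs_replicates <- function(x, ...) {
  n <- nrow(x$mean_bound)
  cat(sprintf("<hs_replicates> %d replicates x %d steps\n",
              length(x$runs), x$config$n_steps))
  cat("  terminal mean bound LA/MA/HA:",
      sprintf("%.1f", x$mean_bound[n, ]), "\n")
  invisible(x)
}
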