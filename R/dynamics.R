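# Elementary stochastic dynamics: movement, binding, cleavage, heparinase
# flux. Each event exists in two forms: a single-agent operation (the unit
# of the model's contract, used directly in tests) and a vectorized phase
# used by the scheduler. Both draw from the ambient R random stream, which
# the runner seeds per replicate.

#' Move one free growth factor by a unit random-walk step
#'
#' A free factor takes one step of fixed length (one patch width) in a
#' uniformly random direction; positions wrap on a torus. Bound factors sit
#' at their cell and cleaved factors take no actions, so for those the call
#' is a no-op.
#'
#' @param state An `hs_state`.
#' @param id Factor index.
#' @param step_length Step length in patch widths (default 1).
#' @return The updated state.
#' @export
move_growth_factor <- function(state, id, step_length = 1) {
  if (state$factors$state[id] != FS_FREE) return(state)
  theta <- stats::runif(1, 0, 2 * pi)
  state$factors$x[id] <- (state$factors$x[id] + step_length * cos(theta)) %% state$config$grid_width
  state$factors$y[id] <- (state$factors$y[id] + step_length * sin(theta)) %% state$config$grid_height
  state
}

# Vectorized movement of the factors listed in `ids` (all must be free).
move_phase <- function(state, ids, step_length = 1) {
  n <- length(ids)
  if (n == 0L) return(state)
  theta <- stats::runif(n, 0, 2 * pi)
  state$factors$x[ids] <- (state$factors$x[ids] + step_length * cos(theta)) %% state$config$grid_width
  state$factors$y[ids] <- (state$factors$y[ids] + step_length * sin(theta)) %% state$config$grid_height
  state
}

#' Let one free growth factor attempt to bind in its current patch
#'
#' Among the cells resident in the factor's patch that still carry at least
#' one free binding site, one is chosen uniformly at random; with the
#' class's attachment probability the factor binds to it, occupying one
#' site. A factor makes at most one attempt per step. With no eligible cell
#' nothing happens.
#'
#' @inheritParams move_growth_factor
#' @return The updated state. Whether binding occurred is visible as
#'   `state$factors$state[id]`.
#' @export
attempt_binding <- function(state, id) {
  if (state$factors$state[id] != FS_FREE) return(state)
  p <- patch_index(state$factors$x[id], state$factors$y[id], state$config$grid_width)
  cand <- state$patch_cells[[p]]
  if (is.null(cand)) return(state)
  cand <- cand[state$cells$free_sites[cand] > 0L]
  if (length(cand) == 0L) return(state)
  j <- cand[sample.int(length(cand), 1L)]
  if (stats::runif(1) < state$config$attach_prob[[state$factors$class[id]]]) {
    state$factors$state[id] <- FS_BOUND
    state$factors$cell[id] <- j
    state$factors$x[id] <- state$cells$x[j]
    state$factors$y[id] <- state$cells$y[j]
    state$cells$free_sites[j] <- state$cells$free_sites[j] - 1L
  }
  state
}

# Binding attempts for the free factors in `ids`, processed sequentially in
# the given (pre-shuffled) order so that factors compete for sites within a
# step. Site bookkeeping is done on local copies for speed.
bind_phase <- function(state, ids) {
  if (length(ids) == 0L) return(state)
  W <- state$config$grid_width
  pc <- state$patch_cells
  free_sites <- state$cells$free_sites
  fx <- state$factors$x; fy <- state$factors$y
  fstate <- state$factors$state; fcell <- state$factors$cell
  fclass <- state$factors$class
  ap <- unname(state$config$attach_prob)
  cxv <- state$cells$x; cyv <- state$cells$y

  pat <- patch_index(fx[ids], fy[ids], W)
  for (k in seq_along(ids)) {
    cand <- pc[[pat[k]]]
    if (is.null(cand)) next
    cand <- cand[free_sites[cand] > 0L]
    if (length(cand) == 0L) next
    id <- ids[k]
    j <- cand[sample.int(length(cand), 1L)]
    if (stats::runif(1) < ap[fclass[id]]) {
      fstate[id] <- FS_BOUND
      fcell[id] <- j
      fx[id] <- cxv[j]
      fy[id] <- cyv[j]
      free_sites[j] <- free_sites[j] - 1L
    }
  }
  state$cells$free_sites <- free_sites
  state$factors$x <- fx; state$factors$y <- fy
  state$factors$state <- fstate; state$factors$cell <- fcell
  state
}

#' Cleave one bound growth factor if local heparinase reaches its threshold
#'
#' Deterministic threshold rule: the factor detaches if and only if the
#' heparinase level of the patch containing its bound cell is at or above
#' its class's `cleave_threshold`. Detachment restores one free binding
#' site; the factor's fate follows `config$cleaved_fate` (`degrade`: removed
#' from the active pool; `recycle`: returns to the free pool). Calling on a
#' factor that is not bound is a no-op.
#'
#' Within the scheduler, a factor that bound during the current step is
#' first checked on the following step (see [simulate_step()]).
#'
#' @inheritParams move_growth_factor
#' @return The updated state.
#' @export
cleave_bound_factor <- function(state, id) {
  if (state$factors$state[id] != FS_BOUND) return(state)
  cleave_ids(state, id)
}

# Unconditional-detach helper applied to bound factor ids whose threshold
# test already passed -- plus the test itself in cleave_ids().
cleave_ids <- function(state, ids) {
  j <- state$factors$cell[ids]
  h <- state$heparinase[state$cells$patch[j]]
  th <- unname(state$config$cleave_threshold)[state$factors$class[ids]]
  hit <- h >= th
  if (!any(hit)) return(state)
  ids <- ids[hit]; j <- j[hit]
  state$cells$free_sites <- state$cells$free_sites +
    tabulate(j, nbins = length(state$cells$free_sites))
  state$factors$cell[ids] <- NA_integer_
  state$factors$state[ids] <- if (state$config$cleaved_fate == "degrade") FS_CLEAVED else FS_FREE
  state
}

#' Apply one step of stochastic heparinase flux to every microenvironment
#'
#' Independently for each patch, with probability `flux_prob` the heparinase
#' level changes by an amount drawn uniform on
#' `[-flux_magnitude, +flux_magnitude]`, then is clamped to
#' `[0, heparinase_max]`; otherwise it is unchanged. This is the model's
#' homeostatic removal/replenishment of tissue heparinase.
#'
#' @param state An `hs_state`.
#' @return The updated state.
#' @export
update_heparinase <- function(state) {
  cfg <- state$config
  n <- length(state$heparinase)
  if (cfg$flux_prob <= 0) return(state)
  hit <- stats::runif(n) < cfg$flux_prob
  m <- sum(hit)
  if (m > 0L) {
    delta <- stats::runif(m, -cfg$flux_magnitude, cfg$flux_magnitude)
    state$heparinase[hit] <- pmin(pmax(state$heparinase[hit] + delta, 0), cfg$heparinase_max)
  }
  state
}
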