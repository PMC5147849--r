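# Simulation state and initialization.
#
# The state is a plain list of parallel vectors (struct-of-arrays) so the
# per-step dynamics can be vectorized. Factor state codes: 1 = free,
# 2 = bound, 3 = cleaved (degraded; takes no further actions). Cleaved
# factors are kept in the arrays so per-class mass balance can be read off
# the state at any time.

FS_FREE <- 1L
FS_BOUND <- 2L
FS_CLEAVED <- 3L

# Patch index (1-based, column-major over the lattice) of a continuous
# position. Positions live in [0, W) x [0, H).
patch_index <- function(x, y, grid_width) {
  floor(x) + grid_width * floor(y) + 1L
}

new_factors <- function(n = 0L) {
  list(
    class = integer(n),       # 1=LA, 2=MA, 3=HA
    x = numeric(n), y = numeric(n),
    state = integer(n),       # FS_FREE / FS_BOUND / FS_CLEAVED
    cell = rep(NA_integer_, n)  # index into cells when bound
  )
}

append_factors <- function(f, class, x, y) {
  f$class <- c(f$class, class)
  f$x <- c(f$x, x)
  f$y <- c(f$y, y)
  f$state <- c(f$state, rep(FS_FREE, length(class)))
  f$cell <- c(f$cell, rep(NA_integer_, length(class)))
  f
}

# Map patch index -> integer vector of resident cell indices (NULL if none).
build_patch_cells <- function(cell_patch, n_patches) {
  pc <- vector("list", n_patches)
  if (length(cell_patch)) {
    sp <- split(seq_along(cell_patch), cell_patch)
    pc[as.integer(names(sp))] <- sp
  }
  pc
}

#' Initialize a simulation state
#'
#' Builds the lattice of microenvironments, scatters the stromal cells, draws
#' their binding-site counts and performs the initial cytokine release. The
#' random stream is seeded deterministically from
#' `config$seed + replicate_index`, so a given `(config, replicate_index)`
#' pair always yields the identical initial state.
#'
#' @param config An `hs_config` from [simulation_config()].
#' @param replicate_index Non-negative integer identifying the replicate.
#' @return An object of class `hs_state`: step counter `t`, the per-patch
#'   `heparinase` vector, cell and factor arrays, and the per-class
#'   cumulative release counter `released`.
#' @examples
#' st <- init_simulation(simulation_config(n_steps = 1), 0)
#' length(st$heparinase)  # 2601
#' @export
init_simulation <- function(config, replicate_index = 0L) {
  validate_config(config)
  if (replicate_index < 0) stop("replicate_index must be >= 0", call. = FALSE)
  set.seed(config$seed + as.integer(replicate_index))

  W <- config$grid_width; H <- config$grid_height
  n_patches <- W * H

  heparinase <- if (is.null(config$heparinase_init)) {
    stats::runif(n_patches, 0, config$heparinase_max)
  } else {
    rep(config$heparinase_init, n_patches)
  }

  n <- config$n_cells
  cx <- stats::runif(n, 0, W)
  cy <- stats::runif(n, 0, H)
  total <- pmax(0L, as.integer(round(stats::rnorm(n, config$site_mean, config$site_sd))))
  cells <- list(
    x = cx, y = cy,
    patch = patch_index(cx, cy, W),
    total_sites = total,
    free_sites = total
  )

  state <- list(
    t = 0L,
    config = config,
    heparinase = heparinase,
    cells = cells,
    patch_cells = build_patch_cells(cells$patch, n_patches),
    factors = new_factors(),
    released = c(LA = 0L, MA = 0L, HA = 0L),
    replicate_index = as.integer(replicate_index)
  )
  class(state) <- "hs_state"
  release_cytokines(state, config$initial_release)
}

#' Release free growth factors at uniform random positions
#'
#' Creates the stated number of new free factors of each class, placed
#' uniformly over the lattice, and increments the cumulative release
#' counters. Used both for the one-shot release at t = 0 and for the
#' per-step tumor inflow.
#'
#' @param state An `hs_state`.
#' @param counts_per_class Length-3 non-negative integer vector
#'   (LA, MA, HA).
#' @return The updated state.
#' @export
release_cytokines <- function(state, counts_per_class) {
  counts <- hs_class_int(counts_per_class, "counts_per_class")
  if (any(is.na(counts)) || any(counts < 0))
    stop("invalid configuration: release counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0L) return(state)
  W <- state$config$grid_width; H <- state$config$grid_height
  cls <- rep(1:3, counts)
  state$factors <- append_factors(state$factors, cls,
                                  stats::runif(total, 0, W),
                                  stats::runif(total, 0, H))
  state$released <- state$released + counts
  state
}

# Per-class counts of factors in a given state code.
class_counts <- function(factors, code) {
  tabulate(factors$class[factors$state == code], nbins = 3L)
}

#' Verify the structural invariants of a simulation state
#'
#' Checks site-occupancy conservation (the total number of occupied binding
#' sites equals the number of bound factors, globally and per cell), bounds
#' on the heparinase field, per-class mass balance
#' (bound + free + cleaved = released), and the consistency of the
#' bound-factor/cell cross references.
#'
#' @param state An `hs_state`.
#' @return `TRUE` invisibly; an error describing the violated invariant
#'   otherwise.
#' @export
check_invariants <- function(state) {
  f <- state$factors; cl <- state$cells
  bound <- f$state == FS_BOUND
  if (any(bound & is.na(f$cell)) || any(!bound & !is.na(f$cell)))
    stop("invariant violated: bound <=> cell reference set")
  occupied <- cl$total_sites - cl$free_sites
  if (any(cl$free_sites < 0L) || any(cl$free_sites > cl$total_sites))
    stop("invariant violated: free_sites outside [0, total_sites]")
  if (sum(occupied) != sum(bound))
    stop("invariant violated: occupied sites != bound factors")
  per_cell <- tabulate(f$cell[bound], nbins = length(cl$total_sites))
  if (!all(per_cell == occupied))
    stop("invariant violated: per-cell occupancy mismatch")
  if (any(state$heparinase < 0) || any(state$heparinase > state$config$heparinase_max))
    stop("invariant violated: heparinase outside [0, heparinase_max]")
  counts <- class_counts(f, FS_FREE) + class_counts(f, FS_BOUND) +
    class_counts(f, FS_CLEAVED)
  if (!all(counts == unname(state$released)))
    stop("invariant violated: per-class mass balance (bound+free+cleaved != released)")
  invisible(TRUE)
}

#' @export
print.hs_state <- function(x, ...) {
  b <- class_counts(x$factors, FS_BOUND)
  fr <- class_counts(x$factors, FS_FREE)
  cv <- class_counts(x$factors, FS_CLEAVED)
  cat(sprintf("<hs_state> t=%d, %d patches, %d cells (%d/%d sites free)\n",
              x$t, length(x$heparinase), length(x$cells$x),
              sum(x$cells$free_sites), sum(x$cells$total_sites)))
  cat(sprintf("  bound   LA=%d MA=%d HA=%d\n", b[1], b[2], b[3]))
  cat(sprintf("  free    LA=%d MA=%d HA=%d\n", fr[1], fr[2], fr[3]))
  cat(sprintf("  cleaved LA=%d MA=%d HA=%d\n", cv[1], cv[2], cv[3]))
  invisible(x)
}
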