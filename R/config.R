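#' Build a validated simulation configuration
#'
#' Collects every model parameter into one record and validates it, including
#' the strict affinity ordering of the cleavage thresholds
#' (`LA < MA < HA`, see [validate_affinity_ordering()]).
#'
#' Per-class arguments (`attach_prob`, `cleave_threshold`, `initial_release`,
#' `inflow_per_step`) accept either a single value, recycled to all three
#' classes, or a length-3 vector in (or named by) the order `LA, MA, HA`.
#'
#' @param grid_width,grid_height Lattice extent in patches. The default
#'   51 x 51 lattice holds 2601 microenvironments.
#' @param n_cells Number of immobile stromal cells scattered uniformly over
#'   the lattice.
#' @param site_mean,site_sd Mean and standard deviation of the per-cell
#'   binding-site count; counts are drawn from a normal distribution, rounded
#'   to the nearest integer and clamped at zero.
#' @param attach_prob Per-class probability that a factor co-located with a
#'   cell carrying a free site attaches to it (one attempt per step).
#' @param cleave_threshold Per-class heparinase level (arbitrary units, on
#'   the same scale as `heparinase_max`) at or above which a bound factor is
#'   cleaved. Must be strictly increasing LA < MA < HA.
#' @param initial_release Per-class count of free factors released at t = 0.
#' @param inflow_per_step Per-class count of additional free factors released
#'   at the start of every step. All zero is wound-healing mode; any positive
#'   entry is tumor mode.
#' @param heparinase_max Upper bound of the per-patch heparinase level.
#' @param heparinase_init Either `NULL` (each patch initialized independently
#'   uniform on `[0, heparinase_max]`) or a single number giving a constant
#'   initial field -- useful for controlled experiments such as the
#'   single-site occupancy chain.
#' @param flux_prob Per-patch, per-step probability that the heparinase level
#'   changes.
#' @param flux_magnitude Maximal absolute size of one heparinase change; the
#'   change is drawn uniform on `[-flux_magnitude, +flux_magnitude]` and the
#'   result clamped to `[0, heparinase_max]`.
#' @param cleaved_fate What happens to a cleaved factor: `"degrade"` (removed
#'   from the active pool) or `"recycle"` (returns to the free pool and
#'   resumes its random walk).
#' @param n_steps Number of scheduler steps per run.
#' @param n_replicates Number of independent replicate runs.
#' @param seed Base random seed; replicate `r` uses `seed + r`.
#' @return An object of class `hs_config` (a named list of the above).
#' @examples
#' cfg <- simulation_config(n_steps = 10, n_replicates = 2)
#' cfg$grid_width * cfg$grid_height  # 2601 microenvironments
#' @seealso [load_config()], [validate_affinity_ordering()]
#' @export
simulation_config <- function(grid_width = 51L,
                              grid_height = 51L,
                              n_cells = 200L,
                              site_mean = 5,
                              site_sd = 2,
                              attach_prob = c(LA = 0.5, MA = 0.5, HA = 0.5),
                              cleave_threshold = c(LA = 0.25, MA = 0.5, HA = 0.75),
                              initial_release = c(LA = 300L, MA = 300L, HA = 300L),
                              inflow_per_step = c(LA = 0L, MA = 0L, HA = 0L),
                              heparinase_max = 1,
                              heparinase_init = NULL,
                              flux_prob = 0.2,
                              flux_magnitude = 0.1,
                              cleaved_fate = c("degrade", "recycle"),
                              n_steps = 500L,
                              n_replicates = 10L,
                              seed = 42L) {
  cfg <- list(
    grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height),
    n_cells = as.integer(n_cells),
    site_mean = as.numeric(site_mean),
    site_sd = as.numeric(site_sd),
    attach_prob = hs_class_num(attach_prob, "attach_prob"),
    cleave_threshold = hs_class_num(cleave_threshold, "cleave_threshold"),
    initial_release = hs_class_int(initial_release, "initial_release"),
    inflow_per_step = hs_class_int(inflow_per_step, "inflow_per_step"),
    heparinase_max = as.numeric(heparinase_max),
    heparinase_init = if (is.null(heparinase_init)) NULL else as.numeric(heparinase_init),
    flux_prob = as.numeric(flux_prob),
    flux_magnitude = as.numeric(flux_magnitude),
    cleaved_fate = match.arg(cleaved_fate),
    n_steps = as.integer(n_steps),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  class(cfg) <- "hs_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid configuration: '%s' %s", field, why), call. = FALSE)

  pos_int <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < 1L) bad(field, "must be a positive integer")
  }
  nonneg <- function(field) {
    v <- cfg[[field]]
    if (any(is.na(v)) || any(v < 0)) bad(field, "must be non-negative")
  }

  pos_int("grid_width"); pos_int("grid_height")
  pos_int("n_replicates")
  if (length(cfg$n_steps) != 1L || is.na(cfg$n_steps) || cfg$n_steps < 0L)
    bad("n_steps", "must be a non-negative integer")
  nonneg("n_cells"); nonneg("site_mean"); nonneg("site_sd")
  nonneg("initial_release"); nonneg("inflow_per_step")
  nonneg("flux_magnitude")
  if (is.na(cfg$heparinase_max) || cfg$heparinase_max < 0)
    bad("heparinase_max", "must be non-negative")
  if (any(is.na(cfg$attach_prob)) || any(cfg$attach_prob < 0) || any(cfg$attach_prob > 1))
    bad("attach_prob", "must lie in [0, 1]")
  if (is.na(cfg$flux_prob) || cfg$flux_prob < 0 || cfg$flux_prob > 1)
    bad("flux_prob", "must lie in [0, 1]")
  if (any(is.na(cfg$cleave_threshold)) || any(cfg$cleave_threshold < 0))
    bad("cleave_threshold", "must be non-negative")
  if (!is.null(cfg$heparinase_init) &&
      (cfg$heparinase_init < 0 || cfg$heparinase_init > cfg$heparinase_max))
    bad("heparinase_init", "must lie in [0, heparinase_max]")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  validate_affinity_ordering(cfg)
  invisible(cfg)
}

#' Check the strict affinity ordering of cleavage thresholds
#'
#' The elution order of angiogenesis regulators mandates that low-affinity
#' factors detach at the lowest heparinase level and high-affinity factors at
#' the highest: `cleave_threshold` must satisfy `LA < MA < HA` strictly.
#'
#' @param config An `hs_config` object (or any list with a named
#'   `cleave_threshold` vector).
#' @return `TRUE` invisibly if the ordering holds; otherwise an error naming
#'   the first pair of classes that is out of order.
#' @examples
#' validate_affinity_ordering(simulation_config())
#' @export
validate_affinity_ordering <- function(config) {
  th <- config$cleave_threshold
  for (i in 1:2) {
    lo <- HS_CLASSES[i]; hi <- HS_CLASSES[i + 1L]
    if (!(th[[lo]] < th[[hi]]))
      stop(sprintf(
        "invalid configuration: 'cleave_threshold' violates affinity ordering: %s (%g) must be strictly below %s (%g)",
        lo, th[[lo]], hi, th[[hi]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.hs_config <- function(x, ...) {
  cat("<hs_config>\n")
  cat(sprintf("  lattice: %d x %d (%d microenvironments), %d cells, sites ~ N(%g, %g)\n",
              x$grid_width, x$grid_height, x$grid_width * x$grid_height,
              x$n_cells, x$site_mean, x$site_sd))
  cat(sprintf("  attach_prob: LA=%g MA=%g HA=%g\n",
              x$attach_prob[["LA"]], x$attach_prob[["MA"]], x$attach_prob[["HA"]]))
  cat(sprintf("  cleave_threshold: LA=%g MA=%g HA=%g (heparinase_max=%g)\n",
              x$cleave_threshold[["LA"]], x$cleave_threshold[["MA"]],
              x$cleave_threshold[["HA"]], x$heparinase_max))
  cat(sprintf("  release at t=0: LA=%d MA=%d HA=%d; inflow/step: LA=%d MA=%d HA=%d (%s mode)\n",
              x$initial_release[["LA"]], x$initial_release[["MA"]], x$initial_release[["HA"]],
              x$inflow_per_step[["LA"]], x$inflow_per_step[["MA"]], x$inflow_per_step[["HA"]],
              if (any(x$inflow_per_step > 0)) "tumor" else "wound-healing"))
  cat(sprintf("  heparinase flux: prob=%g magnitude=%g; cleaved factors: %s\n",
              x$flux_prob, x$flux_magnitude, x$cleaved_fate))
  cat(sprintf("  %d steps x %d replicates, seed %d\n",
              x$n_steps, x$n_replicates, x$seed))
  invisible(x)
}
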