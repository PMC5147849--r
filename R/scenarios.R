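# Presets for the published simulation experiments. The wound-healing
# preset is a one-shot release at t = 0 with zero inflow; the tumor presets
# add a constant per-step inflow of stimulators (and in some variants
# stabilizers/inhibitors) on top of the same one-shot release.

SCENARIO_REGISTRY <- list(
  wound_healing = c(LA = 0L, MA = 0L, HA = 0L),
  B             = c(LA = 1L, MA = 0L, HA = 0L),
  C             = c(LA = 1L, MA = 1L, HA = 0L),
  D             = c(LA = 2L, MA = 1L, HA = 0L),
  E             = c(LA = 5L, MA = 1L, HA = 0L),
  F             = c(LA = 5L, MA = 1L, HA = 1L),
  S8            = c(LA = 5L, MA = 1L, HA = 2L)
)

new_scenario <- function(name) {
  out <- list(name = name, inflow_per_step = SCENARIO_REGISTRY[[name]])
  class(out) <- "hs_scenario"
  out
}

#' The normal wound-healing scenario
#'
#' One-shot cytokine release at t = 0, zero per-step inflow. This is the
#' baseline experiment whose averaged curves show the sequential
#' LA-then-MA-then-HA pattern resolving into inhibitor dominance.
#'
#' @return An `hs_scenario` with inflow (0, 0, 0).
#' @export
wound_healing_scenario <- function() new_scenario("wound_healing")

#' Tumor-angiogenesis scenarios (continuous stimulator inflow)
#'
#' Presets named after the published panels: per-step inflow of
#' \itemize{
#'   \item `B`: 1 LA
#'   \item `C`: 1 LA, 1 MA
#'   \item `D`: 2 LA, 1 MA
#'   \item `E`: 5 LA, 1 MA
#'   \item `F`: 5 LA, 1 MA, 1 HA
#'   \item `S8`: 5 LA, 1 MA, 2 HA
#' }
#' on top of the standard one-shot release.
#'
#' @param name One of `"B"`, `"C"`, `"D"`, `"E"`, `"F"`, `"S8"`.
#' @return An `hs_scenario`.
#' @examples
#' tumor_scenario("E")$inflow_per_step
#' @export
tumor_scenario <- function(name) {
  valid <- setdiff(names(SCENARIO_REGISTRY), "wound_healing")
  if (length(name) != 1L || !name %in% valid)
    stop(sprintf("unknown tumor scenario %s; valid names: %s",
                 deparse(name), paste(valid, collapse = ", ")), call. = FALSE)
  new_scenario(name)
}

#' List all registered scenario presets
#'
#' @return Named list mapping each scenario name to its (LA, MA, HA) inflow
#'   triple.
#' @export
list_scenarios <- function() SCENARIO_REGISTRY

#' Look up a scenario preset by name
#'
#' Accepts any registered name, including `"wound_healing"`.
#'
#' @inheritParams tumor_scenario
#' @return An `hs_scenario`.
#' @export
get_scenario <- function(name) {
  if (length(name) != 1L || !name %in% names(SCENARIO_REGISTRY))
    stop(sprintf("unknown scenario %s; valid names: %s", deparse(name),
                 paste(names(SCENARIO_REGISTRY), collapse = ", ")), call. = FALSE)
  new_scenario(name)
}

#' Apply a scenario preset to a configuration
#'
#' Overwrites the configuration's `inflow_per_step` with the scenario's
#' triple, leaving every other parameter unchanged.
#'
#' @param scenario An `hs_scenario` (or a scenario name).
#' @param config Base `hs_config`; defaults to [simulation_config()].
#' @return The modified, revalidated `hs_config`.
#' @examples
#' cfg <- apply_scenario(tumor_scenario("E"))
#' cfg$inflow_per_step
#' @export
apply_scenario <- function(scenario, config = simulation_config()) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  config$inflow_per_step <- scenario$inflow_per_step
  validate_config(config)
  config
}

#' @export
print.hs_scenario <- function(x, ...) {
  cat(sprintf("<hs_scenario> %s: inflow/step LA=%d MA=%d HA=%d\n", x$name,
              x$inflow_per_step[["LA"]], x$inflow_per_step[["MA"]],
              x$inflow_per_step[["HA"]]))
  invisible(x)
}
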