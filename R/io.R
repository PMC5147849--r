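# Configuration files, CSV serialization and the self-describing output
# bundle. Config files are flat key-value documents (YAML or JSON); the
# per-class parameters use `_la` / `_ma` / `_ha` suffixed keys. CSVs carry
# the fixed column set step, class, bound_count, free_count,
# replicate_index in step-major order with classes LA < MA < HA.

CONFIG_SCALAR_KEYS <- c(
  "grid_width", "grid_height", "n_cells", "site_mean", "site_sd",
  "heparinase_max", "heparinase_init", "flux_prob", "flux_magnitude",
  "cleaved_fate", "n_steps", "n_replicates", "seed"
)
CONFIG_CLASS_KEYS <- c("attach_prob", "cleave_threshold",
                       "initial_release", "inflow_per_step")

config_flat_keys <- function() {
  c(CONFIG_SCALAR_KEYS,
    unlist(lapply(CONFIG_CLASS_KEYS,
                  function(k) paste(k, tolower(HS_CLASSES), sep = "_"))))
}

flatten_config <- function(config) {
  out <- list()
  for (k in CONFIG_SCALAR_KEYS) {
    v <- config[[k]]
    if (!is.null(v)) out[[k]] <- unname(v)
  }
  for (k in CONFIG_CLASS_KEYS)
    for (cl in HS_CLASSES)
      out[[paste(k, tolower(cl), sep = "_")]] <- unname(config[[k]][[cl]])
  out
}

#' Load a simulation configuration from a YAML or JSON file
#'
#' The file is a flat key-value document; any subset of the configuration
#' fields may be given (missing fields take their defaults, so an empty
#' document yields the full default configuration). Per-class parameters
#' use suffixed keys, e.g. `attach_prob_la`, `cleave_threshold_ha`,
#' `initial_release_ma`, `inflow_per_step_la`. Unknown keys are rejected
#' with an error listing them; the loaded configuration is fully validated,
#' including the affinity ordering of the cleavage thresholds.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `hs_config`.
#' @seealso [save_config()], [simulation_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) {
    stop(sprintf("could not parse config file %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop(sprintf("config file %s is not a key-value document", path), call. = FALSE)
  unknown <- setdiff(names(raw), config_flat_keys())
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  config_from_flat(raw)
}

config_from_flat <- function(raw) {
  args <- list()
  for (k in CONFIG_SCALAR_KEYS) if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  for (k in CONFIG_CLASS_KEYS) {
    keys <- paste(k, tolower(HS_CLASSES), sep = "_")
    if (any(keys %in% names(raw))) {
      default <- formals(simulation_config)[[k]]
      v <- hs_class_vec(eval(default), k)
      for (i in 1:3) if (!is.null(raw[[keys[i]]])) v[[i]] <- raw[[keys[i]]]
      args[[k]] <- v
    }
  }
  do.call(simulation_config, args)
}

#' Save a simulation configuration as a flat YAML document
#'
#' Writes every field with 15 significant digits so that
#' `load_config(save_config(cfg, p))` reproduces `cfg`.
#'
#' @param config An `hs_config`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  writeLines(yaml::as.yaml(flatten_config(config), precision = 15), path)
  invisible(path)
}

timeseries_df <- function(x) {
  if (inherits(x, "hs_run")) {
    bound <- x$bound; free <- x$free
    rep_id <- as.character(x$replicate_index)
  } else if (inherits(x, "hs_replicates")) {
    bound <- x$mean_bound; free <- x$mean_free
    rep_id <- "mean"
  } else {
    stop("expected an hs_run or hs_replicates object", call. = FALSE)
  }
  steps <- seq_len(nrow(bound)) - 1L
  data.frame(
    step = rep(steps, each = 3L),
    class = rep(HS_CLASSES, times = length(steps)),
    bound_count = as.vector(t(bound)),
    free_count = as.vector(t(free)),
    replicate_index = rep_id,
    stringsAsFactors = FALSE
  )
}

#' Write a run or replicate summary as CSV
#'
#' Fixed column set `step, class, bound_count, free_count,
#' replicate_index`, step-major row order with classes LA < MA < HA;
#' `replicate_index` is `"mean"` for a replicate summary. The file is
#' written to a temporary name and renamed into place, so no partial CSV is
#' ever left behind on error.
#'
#' @param result An `hs_run` or `hs_replicates`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(result, path) {
  df <- timeseries_df(result)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("cannot write %s: directory does not exist", path), call. = FALSE)
  tmp <- tempfile(tmpdir = dir, fileext = ".csv.tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path))
    stop(sprintf("cannot write %s", path), call. = FALSE)
  invisible(path)
}

#' Read a time-series CSV back into a data frame
#'
#' @param path A CSV written by [write_timeseries_csv()].
#' @return A data frame with the fixed column set.
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(replicate_index = "character"))
  need <- c("step", "class", "bound_count", "free_count", "replicate_index")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Reconstruct a bound-series matrix from a time-series data frame
#'
#' If several replicate indices are present the `"mean"` rows are used when
#' available; otherwise the frame must hold a single replicate.
#'
#' @param df A data frame from [read_timeseries_csv()] (or a path).
#' @return A numeric matrix, rows t = 0..n_steps, columns LA, MA, HA.
#' @export
bound_series_from_csv <- function(df) {
  if (is.character(df)) df <- read_timeseries_csv(df)
  reps <- unique(df$replicate_index)
  if (length(reps) > 1L) {
    if (!"mean" %in% reps)
      stop("CSV holds multiple replicates and no 'mean' rows", call. = FALSE)
    df <- df[df$replicate_index == "mean", ]
  }
  steps <- sort(unique(df$step))
  m <- matrix(NA_real_, nrow = length(steps), ncol = 3L,
              dimnames = list(step = steps, class = HS_CLASSES))
  for (cl in HS_CLASSES) {
    sub <- df[df$class == cl, ]
    m[match(sub$step, steps), cl] <- sub$bound_count
  }
  if (anyNA(m)) stop("CSV does not cover every (step, class) pair", call. = FALSE)
  m
}

#' Write a self-describing output bundle for a replicate set
#'
#' Creates (under `dir`): one CSV per replicate (`replicate_<i>.csv`), the
#' averaged `summary.csv`, the classifier verdict (`verdict.txt`), an echo
#' of the configuration (`config.yaml`) and a run manifest
#' (`manifest.txt`: seed, replicate count, package version, timestamp).
#' The config echo plus the manifest's seed reproduce every CSV exactly.
#'
#' @param reps An `hs_replicates` from [run_replicates()].
#' @param dir Output directory (created if needed).
#' @param tail_fraction,dominance_ratio Passed to [classify_pattern()].
#' @return The verdict (`hs_verdict`), invisibly.
#' @export
write_output_bundle <- function(reps, dir, tail_fraction = 0.2,
                                dominance_ratio = 1) {
  if (!inherits(reps, "hs_replicates"))
    stop("expected an hs_replicates object", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (run in reps$runs)
    write_timeseries_csv(run, file.path(dir, sprintf("replicate_%d.csv", run$replicate_index)))
  write_timeseries_csv(reps, file.path(dir, "summary.csv"))
  save_config(reps$config, file.path(dir, "config.yaml"))
  verdict <- classify_pattern(reps, tail_fraction, dominance_ratio)
  writeLines(utils::capture.output(print(verdict)), file.path(dir, "verdict.txt"))
  writeLines(c(
    sprintf("package: hscompete %s", as.character(utils::packageVersion("hscompete"))),
    sprintf("seed: %d", reps$config$seed),
    sprintf("n_replicates: %d", reps$config$n_replicates),
    sprintf("n_steps: %d", reps$config$n_steps),
    sprintf("written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), file.path(dir, "manifest.txt"))
  invisible(verdict)
}
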