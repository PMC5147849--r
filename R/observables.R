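# Time-series summaries and the qualitative pattern classifier separating
# resolved sequential signaling (normal wound healing) from unresolved
# stimulation (tumor-like continuous inflow).

as_bound_matrix <- function(x) {
  if (inherits(x, "hs_replicates")) return(x$mean_bound)
  if (inherits(x, "hs_run")) return(x$bound)
  x <- as.matrix(x)
  if (ncol(x) != 3L)
    stop("bound series must have 3 columns (LA, MA, HA)", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- HS_CLASSES
  x[, HS_CLASSES, drop = FALSE]
}

#' Step index of a series' peak
#'
#' Returns the step (t = 0-based row index) at which a bound-count series
#' attains its maximum; ties are broken toward the earliest step. For a
#' matrix (columns LA, MA, HA) a named vector of per-class peak steps is
#' returned.
#'
#' @param series Numeric vector, or a bound-series matrix / `hs_run` /
#'   `hs_replicates` object.
#' @return Integer step index (0-based), or a named vector of them.
#' @examples
#' peak_time(c(0, 3, 1, 0))  # 1
#' @export
peak_time <- function(series) {
  if (is.numeric(series) && is.null(dim(series))) {
    if (length(series) == 0L) stop("empty series", call. = FALSE)
    return(which.max(series) - 1L)
  }
  m <- as_bound_matrix(series)
  if (nrow(m) == 0L) stop("empty series", call. = FALSE)
  vapply(HS_CLASSES, function(k) which.max(m[, k]) - 1L, integer(1))
}

#' Pointwise mean of replicate bound series
#'
#' @param results A list of bound-series matrices (or `hs_run` objects), all
#'   of identical dimension.
#' @return The elementwise arithmetic mean matrix.
#' @export
average_replicates <- function(results) {
  if (length(results) == 0L) stop("no series to average", call. = FALSE)
  mats <- lapply(results, as_bound_matrix)
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("series length mismatch across replicates", call. = FALSE)
  Reduce(`+`, mats) / length(mats)
}

tail_window <- function(m, tail_fraction) {
  if (!is.numeric(tail_fraction) || length(tail_fraction) != 1L ||
      is.na(tail_fraction) || tail_fraction <= 0 || tail_fraction > 1)
    stop("tail_fraction must lie in (0, 1]", call. = FALSE)
  n <- nrow(m)
  w <- max(1L, as.integer(ceiling(tail_fraction * n)))
  m[(n - w + 1L):n, , drop = FALSE]
}

#' Per-class share of terminal binding-site occupancy
#'
#' Mean bound count per class over the final window of the run (the last
#' `tail_fraction` of recorded steps), normalized to shares summing to 1.
#' An all-zero window yields zero shares with attribute `no_signal = TRUE`.
#'
#' @param summary A bound-series matrix or `hs_run` / `hs_replicates`.
#' @param tail_fraction Fraction (0, 1] of the series forming the terminal
#'   window.
#' @return Named numeric vector of shares (LA, MA, HA).
#' @export
terminal_occupancy <- function(summary, tail_fraction = 0.2) {
  m <- as_bound_matrix(summary)
  tw <- tail_window(m, tail_fraction)
  means <- colMeans(tw)
  tot <- sum(means)
  if (tot == 0) {
    out <- c(LA = 0, MA = 0, HA = 0)
    attr(out, "no_signal") <- TRUE
    return(out)
  }
  means / tot
}

#' Classify an averaged bound time series as resolved or unresolved
#'
#' Operationalizes the qualitative distinction between normal wound healing
#' and tumor-like signaling. The verdict is
#' \describe{
#'   \item{`sequential_resolved`}{the class peaks occur in affinity order
#'     (`peak(LA) <= peak(MA) <= peak(HA)`) \emph{and} high-affinity factors
#'     dominate the terminal window: mean bound HA over the final
#'     `tail_fraction` of steps is at least `dominance_ratio` times the mean
#'     bound LA + MA there. The one-shot release resolves into inhibitor
#'     dominance.}
#'   \item{`unresolved_stimulation`}{stimulators/stabilizers out-compete the
#'     inhibitors to the end: terminal mean LA + MA exceeds terminal mean
#'     HA.}
#'   \item{`no_signal`}{all series identically zero.}
#' }
#' A series that falls in neither branch (possible when `dominance_ratio >
#' 1`, or when HA dominates without ordered peaks) is assigned the verdict
#' nearer by the dominance criterion; both diagnostics are always reported.
#'
#' @inheritParams terminal_occupancy
#' @param dominance_ratio Required ratio of terminal HA to terminal LA + MA
#'   for the resolved verdict (default 1).
#' @return An `hs_verdict`: `label`, per-class `peak_times`,
#'   `terminal_shares`, the terminal `tail_means`, and the thresholds used.
#' @examples
#' m <- cbind(LA = c(5, 2, 0, 0), MA = c(2, 4, 1, 0), HA = c(0, 2, 5, 6))
#' classify_pattern(m)$label
#' @export
classify_pattern <- function(summary, tail_fraction = 0.2, dominance_ratio = 1) {
  m <- as_bound_matrix(summary)
  if (nrow(m) == 0L) stop("empty series", call. = FALSE)
  tw <- tail_window(m, tail_fraction)
  tail_means <- colMeans(tw)
  peaks <- peak_time(m)
  shares <- terminal_occupancy(m, tail_fraction)

  if (all(m == 0)) {
    label <- "no_signal"
  } else {
    stim <- tail_means[["LA"]] + tail_means[["MA"]]
    peaks_ordered <- peaks[["LA"]] <= peaks[["MA"]] && peaks[["MA"]] <= peaks[["HA"]]
    dominant <- tail_means[["HA"]] >= dominance_ratio * stim
    label <- if (dominant && peaks_ordered) {
      "sequential_resolved"
    } else if (stim > tail_means[["HA"]]) {
      "unresolved_stimulation"
    } else if (dominant) {
      "sequential_resolved"   # HA-dominant but peaks unordered: nearest verdict
    } else {
      "unresolved_stimulation"  # between 1x and dominance_ratio x: not resolved
    }
  }

  out <- list(
    label = label,
    peak_times = peaks,
    terminal_shares = shares,
    tail_means = tail_means,
    tail_fraction = tail_fraction,
    dominance_ratio = dominance_ratio
  )
  class(out) <- "hs_verdict"
  out
}

#' @export
print.hs_verdict <- function(x, ...) {
  cat(sprintf("<hs_verdict> %s\n", x$label))
  cat(sprintf("  peak steps: LA=%d MA=%d HA=%d\n",
              x$peak_times[["LA"]], x$peak_times[["MA"]], x$peak_times[["HA"]]))
  cat(sprintf("  terminal shares (tail %.0f%%): LA=%.3f MA=%.3f HA=%.3f\n",
              100 * x$tail_fraction, x$terminal_shares[["LA"]],
              x$terminal_shares[["MA"]], x$terminal_shares[["HA"]]))
  cat(sprintf("  terminal means: LA=%.2f MA=%.2f HA=%.2f (dominance ratio %.2f)\n",
              x$tail_means[["LA"]], x$tail_means[["MA"]], x$tail_means[["HA"]],
              x$dominance_ratio))
  invisible(x)
}
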