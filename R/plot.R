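#' Plot averaged bound time series
#'
#' Bound factor counts per class against simulation step, one line per
#' affinity class, in the style of the model's summary figures.
#'
#' @param x An `hs_replicates` (the averaged series is drawn) or `hs_run`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.hs_replicates <- function(x, ...) {
  plot_bound_series(x$mean_bound,
                    main = sprintf("Mean bound factors (%d replicates)",
                                   length(x$runs)), ...)
  invisible(x)
}

#' @rdname plot.hs_replicates
#' @export
plot.hs_run <- function(x, ...) {
  plot_bound_series(x$bound,
                    main = sprintf("Bound factors (replicate %d)",
                                   x$replicate_index), ...)
  invisible(x)
}

plot_bound_series <- function(m, main = "Bound factors", ...) {
  graphics::matplot(seq_len(nrow(m)) - 1L, m, type = "l", lty = 1, lwd = 2,
                    col = c("#D55E00", "#0072B2", "#009E73"),
                    xlab = "step", ylab = "bound factors", main = main, ...)
  graphics::legend("topright", legend = HS_CLASSES, lty = 1, lwd = 2,
                   col = c("#D55E00", "#0072B2", "#009E73"), bty = "n")
}
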