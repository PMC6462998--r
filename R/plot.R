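# Static plotting helpers (base graphics).

#' Raster plot of one layer
#'
#' @param spikes a [SpikeData-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotRaster <- function(spikes, ...) {
  ev <- spikes@events
  graphics::plot(ev$time, ev$neuron, pch = ".", cex = 2,
                 xlim = c(0, spikes@duration), ylim = c(0.5, spikes@n + 0.5),
                 xlab = "time (ms)", ylab = "neuron",
                 main = spikes@layer, ...)
  invisible(NULL)
}

#' Windowed LIP rate plot
#'
#' @param trace a [DecisionTrace-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotLipRates <- function(trace, ...) {
  ylim <- range(0, trace@left, trace@right)
  graphics::plot(trace@times, trace@left, type = "l", col = "blue",
                 ylim = ylim, xlab = "window start (ms)", ylab = "rate (Hz)",
                 ...)
  graphics::lines(trace@times, trace@right, col = "red")
  graphics::legend("topleft", legend = c("left", "right"), lty = 1,
                   col = c("blue", "red"), bty = "n")
  if (!is.na(trace@latency))
    graphics::abline(v = trace@latency, lty = 2)
  invisible(NULL)
}
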