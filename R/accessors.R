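# Accessors and show methods for the core containers.

#' Number of frames in a FrameSequence
#' @param x a FrameSequence.
#' @return integer frame count.
#' @export
nFrames <- function(x) dim(x@frames)[1]

#' Frame interval (ms)
#' @param x a FrameSequence.
#' @return frame interval in ms.
#' @export
frameInterval <- function(x) x@frameInterval

#' Pixel scale (px per degree of visual angle)
#' @param x a FrameSequence.
#' @return pixels per degree.
#' @export
pxPerDegree <- function(x) x@pxPerDegree

#' Stimulus duration (ms)
#' @param x a FrameSequence.
#' @return duration in ms.
#' @export
stimulusDuration <- function(x) nFrames(x) * x@frameInterval

#' Stimulus/run metadata
#' @param x a FrameSequence or SimulationResult.
#' @return named metadata list.
#' @export
stimulusMetadata <- function(x) {
  if (is(x, "SimulationResult")) x@stimulusMeta else x@metadata
}

#' Spike events of a layer
#' @param x a SpikeData or SimulationResult.
#' @param layer layer label (for SimulationResult).
#' @return data.frame with columns neuron, time.
#' @export
spikeEvents <- function(x, layer = NULL) {
  if (is(x, "SimulationResult")) {
    if (is.null(layer)) stop("give a layer label")
    x <- x@spikes[[layer]]
  }
  x@events
}

#' Layer spikes of a simulation result
#' @param x a SimulationResult.
#' @param layer layer label.
#' @return a SpikeData object.
#' @export
layerSpikes <- function(x, layer) x@spikes[[layer]]

#' Synapse table of a ConnectionSet
#' @param x a ConnectionSet.
#' @return data.frame pre, post, weight, delay.
#' @export
synapses <- function(x) x@synapses

#' Preferred angles of a map
#' @param x an OrientationMap.
#' @return matrix of preferred angles (rad).
#' @export
mapTheta <- function(x) x@theta

#' Receptive-field phases of a map
#' @param x an OrientationMap.
#' @return matrix of phases (rad).
#' @export
mapPhase <- function(x) x@phase

#' Decoded angle in degrees
#' @param x a DecodeResult.
#' @return angle in degrees, NA when undefined.
#' @export
decodedAngle <- function(x) x@estimate

#' Decision of a DecisionTrace
#' @param x a DecisionTrace.
#' @return "left", "right" or "undecided".
#' @export
decision <- function(x) x@decision

#' Decision latency (ms)
#' @param x a DecisionTrace.
#' @return ms at which the winner starts to prevail, NA when undecided.
#' @export
decisionLatency <- function(x) x@latency

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d px, %.2f ms/frame (%.0f ms)\n",
              d[1], d[2], d[3], object@frameInterval,
              d[1] * object@frameInterval))
  cat(sprintf("  %.2f px/degree\n", object@pxPerDegree))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "DotField", function(object) {
  cat(sprintf("DotField: %d dots (%d radial, %d random), center (%.1f, %.1f) px\n",
              nrow(object@positions), sum(object@isRadial),
              sum(!object@isRadial), object@center[1], object@center[2]))
  cat(sprintf("  speed %.1f px/s, lifetime %.0f ms, screen %d px\n",
              object@speed, object@lifetime, as.integer(object@sizePx)))
})

setMethod("show", "SpikeData", function(object) {
  cat(sprintf("SpikeData '%s': %d spikes from %d neurons over %.0f ms\n",
              object@layer, nrow(object@events), object@n, object@duration))
})

setMethod("show", "ConnectionSet", function(object) {
  s <- object@synapses
  cat(sprintf("ConnectionSet %s -> %s: %d synapses", object@pre, object@post,
              nrow(s)))
  if (nrow(s))
    cat(sprintf(" (weights %.3g .. %.3g)", min(s$weight), max(s$weight)))
  cat("\n")
})

setMethod("show", "OrientationMap", function(object) {
  cat(sprintf("OrientationMap %d x %d, period %s, lambda %.1f, seed %d\n",
              object@dims[1], object@dims[2],
              if (isTRUE(all.equal(object@period, pi))) "pi" else "2*pi",
              object@lambda, object@seed))
})

setMethod("show", "Network", function(object) {
  cat("Network with layers:\n")
  print(object@layers[, c("label", "n", "model")], row.names = FALSE)
  nsyn <- sum(vapply(object@connections, function(cs) nrow(cs@synapses), 0))
  cat(sprintf("  %d projections, %d synapses total\n",
              length(object@connections), nsyn))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %.0f ms, layers: %s\n", object@duration,
              paste(names(object@spikes), collapse = ", ")))
})

setMethod("show", "DecodeResult", function(object) {
  if (object@defined)
    cat(sprintf("DecodeResult: %.2f degrees (period %s, %d spikes)\n",
                object@estimate,
                if (isTRUE(all.equal(object@period, pi))) "pi" else "2*pi",
                sum(object@counts)))
  else cat("DecodeResult: undefined (degenerate resultant)\n")
})

setMethod("show", "DecisionTrace", function(object) {
  cat(sprintf("DecisionTrace: %s", object@decision))
  if (!is.na(object@latency)) cat(sprintf(", prevails from %.0f ms", object@latency))
  cat("\n")
})
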