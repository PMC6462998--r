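#' @import methods
NULL

#' Time-ordered stack of grayscale luminance frames
#'
#' The retinal input: a 3-D array of luminance values in [0, 1] with a fixed
#' frame interval and a pixel-to-degree scale. All stimulus generators return
#' this container and the retinal filter consumes it.
#'
#' @slot frames numeric array, `n_frames x height_px x width_px`, values in
#'   [0, 1].
#' @slot frameInterval frame duration in ms.
#' @slot pxPerDegree pixels per degree of visual angle.
#' @slot metadata free-form named list (condition labels, seeds, geometry).
#' @export
setClass("FrameSequence",
  representation(frames = "array", frameInterval = "numeric",
                 pxPerDegree = "numeric", metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "frames must be a 3-D array (frame, row, col)")
    else {
      rng <- range(object@frames)
      if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
        msg <- c(msg, "luminance values must lie in [0, 1]")
    }
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
      msg <- c(msg, "frameInterval must be a single positive number")
    if (length(object@pxPerDegree) != 1L || object@pxPerDegree <= 0)
      msg <- c(msg, "pxPerDegree must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' State of the random-dot kinematogram
#'
#' Mutable state of the 50-dot flow field: positions and unit motion
#' directions, per-dot ages against the 100 ms lifetime, the radial/random
#' class labels, and the expansion-center position.
#'
#' Coordinates are in pixels with the origin at the screen center, x
#' rightward and y upward.
#'
#' @slot positions n x 2 matrix, px.
#' @slot directions n x 2 matrix of unit vectors.
#' @slot ages numeric vector, ms, each in [0, lifetime).
#' @slot isRadial logical vector; radial dots always point away from the
#'   expansion center.
#' @slot center length-2 expansion-center position, px.
#' @slot speed dot speed, px/s.
#' @slot sizePx screen side length, px.
#' @slot lifetime dot lifetime, ms.
#' @export
setClass("DotField",
  representation(positions = "matrix", directions = "matrix",
                 ages = "numeric", isRadial = "logical", center = "numeric",
                 speed = "numeric", sizePx = "numeric", lifetime = "numeric"),
  validity = function(object) {
    n <- nrow(object@positions)
    msg <- character()
    if (nrow(object@directions) != n || length(object@ages) != n ||
        length(object@isRadial) != n)
      msg <- c(msg, "positions, directions, ages, isRadial must agree in length")
    if (any(object@ages < 0) || any(object@ages >= object@lifetime))
      msg <- c(msg, "ages must lie in [0, lifetime)")
    nrm <- sqrt(rowSums(object@directions^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "directions must be unit vectors")
    if (any(object@isRadial)) {
      rel <- object@positions[object@isRadial, , drop = FALSE]
      rel[, 1] <- rel[, 1] - object@center[1]
      rel[, 2] <- rel[, 2] - object@center[2]
      d <- object@directions[object@isRadial, , drop = FALSE]
      r <- sqrt(rowSums(rel^2))
      ok <- r < 1e-9 | abs(rowSums(rel * d) / pmax(r, 1e-12) - 1) < 1e-6
      if (!all(ok))
        msg <- c(msg, "radial dots must point away from the expansion center")
    }
    if (length(msg)) msg else TRUE
  })

#' Specification of a multi-region drifting-bar stimulus
#'
#' Each region is a rectangular band of the screen filled with a periodic
#' pattern of bright bar segments that drifts parallel to the bar
#' orientation. Regions must not overlap.
#'
#' @slot regions list; each element a list with fields `yRange` (two numbers,
#'   fraction of screen height measured from the bottom), `orientation`
#'   (rad), `spacing` (px, between bar axes), `width` (px), `speed` (px/s,
#'   drift along the orientation), `segLength` (px), `segGap` (px).
#' @slot duration ms.
#' @export
setClass("BarStimulusSpec",
  representation(regions = "list", duration = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    iv <- t(vapply(object@regions, function(r) sort(r$yRange), numeric(2)))
    if (nrow(iv) > 1) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-9))
        msg <- c(msg, "region overlap: region y-ranges must be disjoint")
    }
    if (length(msg)) msg else TRUE
  })

#' Retinal ganglion cell filter parameters
#'
#' Spatial difference-of-Gaussians (center minus surround, each normalized by
#' its variance) and biphasic temporal kernel built as the difference of two
#' Gamma densities. Distances are in grid units of the 20 x 20 cell lattice.
#'
#' @slot a_c,a_s center/surround amplitudes.
#' @slot sigma_c,sigma_s center/surround widths (grid units), sigma_s > sigma_c.
#' @slot tShape,tScale,tWeight shape (k1, k2), scale (tau1, tau2, ms) and sign
#'   weights (g1, g2) of the two Gamma kernels.
#' @slot tSupport temporal support, ms.
#' @slot gain injected current per unit filter response, pA.
#' @slot gridDim cells per side of the square lattice.
#' @export
setClass("RGCParams",
  representation(a_c = "numeric", a_s = "numeric", sigma_c = "numeric",
                 sigma_s = "numeric", tShape = "numeric", tScale = "numeric",
                 tWeight = "numeric", tSupport = "numeric", gain = "numeric",
                 gridDim = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@sigma_c <= 0 || object@sigma_s <= object@sigma_c)
      msg <- c(msg, "need sigma_s > sigma_c > 0")
    if (length(object@tShape) != 2 || length(object@tScale) != 2 ||
        length(object@tWeight) != 2)
      msg <- c(msg, "temporal kernel needs two shapes, scales and weights")
    else if (all(object@tWeight > 0)) {
      tt <- seq(0, object@tSupport, by = 0.5)
      v <- object@tWeight[1] * stats::dgamma(tt, shape = object@tShape[1],
                                             scale = object@tScale[1]) -
           object@tWeight[2] * stats::dgamma(tt, shape = object@tShape[2],
                                             scale = object@tScale[2])
      s <- sign(v[abs(v) > 1e-12])
      if (sum(diff(s) != 0) != 1L)
        msg <- c(msg, "temporal kernel must be biphasic (exactly one sign change)")
    }
    if (length(msg)) msg else TRUE
  })

#' Per-neuron spike events of one layer
#'
#' @slot layer layer label.
#' @slot events data.frame with columns `neuron` (integer, within-layer id)
#'   and `time` (ms).
#' @slot n number of neurons in the layer.
#' @slot duration simulated duration, ms.
#' @export
setClass("SpikeData",
  representation(layer = "character", events = "data.frame", n = "integer",
                 duration = "numeric"),
  validity = function(object) {
    ev <- object@events
    msg <- character()
    if (!all(c("neuron", "time") %in% names(ev)))
      msg <- c(msg, "events needs columns neuron, time")
    else {
      if (nrow(ev) && (min(ev$time) < 0 || max(ev$time) > object@duration + 1e-9))
        msg <- c(msg, "spike times must lie in [0, duration]")
      if (nrow(ev) && (min(ev$neuron) < 1 || max(ev$neuron) > object@n))
        msg <- c(msg, "neuron ids must lie in 1..n")
    }
    if (length(msg)) msg else TRUE
  })

#' Weighted, delayed synapse list between two layers
#'
#' @slot pre,post layer labels.
#' @slot synapses data.frame with columns `pre`, `post` (within-layer ids),
#'   `weight` (signed; pA for current-based targets, nS for conductance-based
#'   targets) and `delay` (ms).
#' @export
setClass("ConnectionSet",
  representation(pre = "character", post = "character", synapses = "data.frame"),
  validity = function(object) {
    need <- c("pre", "post", "weight", "delay")
    if (!all(need %in% names(object@synapses)))
      return("synapses needs columns pre, post, weight, delay")
    if (nrow(object@synapses) && any(object@synapses$delay <= 0))
      return("delays must be positive")
    TRUE
  })

#' Pinwheel-structured preference map
#'
#' Preferred angle per grid cell, generated by superposing random complex
#' plane waves of a fixed wavenumber; the argument of the superposition,
#' mapped onto the period, yields the characteristic pinwheel layout. A
#' second independent realization provides the receptive-field phase map.
#'
#' @slot dims grid dimensions (rows, cols).
#' @slot theta matrix of preferred angles: in [0, pi) for orientation maps,
#'   [0, 2*pi) for direction maps.
#' @slot phase matrix of receptive-field phases in [0, 2*pi).
#' @slot lambda generating wavelength (grid units).
#' @slot period pi or 2*pi.
#' @slot seed RNG seed used.
#' @export
setClass("OrientationMap",
  representation(dims = "integer", theta = "matrix", phase = "matrix",
                 lambda = "numeric", period = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@theta < 0) || any(object@theta >= object@period + 1e-12))
      msg <- c(msg, "theta must lie within [0, period)")
    if (!isTRUE(all.equal(object@period, pi)) &&
        !isTRUE(all.equal(object@period, 2 * pi)))
      msg <- c(msg, "period must be pi or 2*pi")
    if (length(msg)) msg else TRUE
  })

#' Gabor receptive field
#'
#' Oriented Gaussian envelope multiplied by a cosine carrier running
#' perpendicular to the orientation. Units are lattice grid units.
#'
#' @slot center length-2 position (grid units).
#' @slot orientation rad.
#' @slot phase rad.
#' @slot sigma_x envelope width along the orientation.
#' @slot sigma_y envelope width across the orientation.
#' @slot freq carrier spatial frequency, cycles per grid unit.
#' @export
setClass("GaborRF",
  representation(center = "numeric", orientation = "numeric", phase = "numeric",
                 sigma_x = "numeric", sigma_y = "numeric", freq = "numeric"),
  validity = function(object) {
    if (object@sigma_x <= 0 || object@sigma_y <= 0)
      return("sigmas must be positive")
    TRUE
  })

#' Expansion/contraction template of one MST cell
#'
#' @slot kind "expansion" or "contraction".
#' @slot focal length-2 focal point (grid units); the vertical position is 0.
#' @slot d template concentration (inverse squared grid units).
#' @slot tol direction tolerance (rad) for the binary eligibility pattern.
#' @slot sigma_I width of the MST on-center receptive field (grid units).
#' @slot sigma_ts width of the lateral template-similarity kernel (grid units).
#' @export
setClass("MstTemplateSpec",
  representation(kind = "character", focal = "numeric", d = "numeric",
                 tol = "numeric", sigma_I = "numeric", sigma_ts = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("expansion", "contraction"))
      msg <- c(msg, "kind must be 'expansion' or 'contraction'")
    if (abs(object@focal[2]) > 1e-9)
      msg <- c(msg, "focal points must have vertical position 0")
    if (object@d <= 0) msg <- c(msg, "d must be positive")
    if (length(msg)) msg else TRUE
  })

#' Assembled network
#'
#' Layers, preference maps, all connection sets, and the flattened arrays the
#' simulation engine consumes.
#'
#' @slot config the configuration list the network was built from.
#' @slot layers data.frame census: label, n, model, offset (0-based global id
#'   of the layer's first neuron).
#' @slot maps named list of OrientationMap objects (v1, mt).
#' @slot connections named list of ConnectionSet objects.
#' @slot engine internal list of flattened engine arrays.
#' @export
setClass("Network",
  representation(config = "list", layers = "data.frame", maps = "list",
                 connections = "list", engine = "list"))

#' Result of one full-network simulation
#'
#' @slot spikes named list of SpikeData, one per layer.
#' @slot stimulusMeta metadata list of the driving stimulus.
#' @slot config config snapshot (with the seeds actually used), sufficient to
#'   reproduce the run bit-for-bit.
#' @slot duration ms.
#' @export
setClass("SimulationResult",
  representation(spikes = "list", stimulusMeta = "list", config = "list",
                 duration = "numeric"))

#' Population-vector decode result
#'
#' @slot estimate decoded angle in degrees, within the period; NA when the
#'   resultant vector is degenerate (no spikes or exact cancellation).
#' @slot counts per-neuron spike counts used.
#' @slot preferences per-neuron preferred angles (rad).
#' @slot period pi or 2*pi.
#' @slot defined FALSE when the decode is degenerate.
#' @export
setClass("DecodeResult",
  representation(estimate = "numeric", counts = "numeric",
                 preferences = "numeric", period = "numeric",
                 defined = "logical"))

#' Left/right decision trace
#'
#' @slot times window start times, ms.
#' @slot left,right windowed firing rates, Hz.
#' @slot decision "left", "right" or "undecided".
#' @slot latency ms at which the eventual winner starts to prevail
#'   permanently; NA when undecided.
#' @slot window window length, ms.
#' @export
setClass("DecisionTrace",
  representation(times = "numeric", left = "numeric", right = "numeric",
                 decision = "character", latency = "numeric",
                 window = "numeric"))
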