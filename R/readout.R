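# Population decoding and the left/right decision analysis.

#' Population-vector decode of spike counts
#'
#' Estimates the stimulus angle as the argument of the spike-count-weighted
#' sum of unit vectors at the cells' preferred angles:
#' est = atan2(sum n_i sin theta'_i, sum n_i cos theta'_i). For orientation
#' decoding (period pi) the preferred angles are doubled before averaging and
#' the result halved, the standard circular-statistics treatment of axial
#' data; for direction decoding (period 2*pi) the angles enter unchanged.
#'
#' @param spikes a [SpikeData-class].
#' @param preferences preferred angles (rad): a numeric vector for neurons
#'   1..length(preferences), or an [OrientationMap-class] covering the
#'   layer's excitatory grid.
#' @param interval time window c(from, to), ms; default the whole trial.
#' @param period pi (orientation) or 2*pi (direction); defaults to the map's
#'   period, or pi for a numeric preference vector.
#' @return a [DecodeResult-class]; `defined` is FALSE (estimate NA) when no
#'   spikes fall in the window or the resultant vector vanishes.
#' @export
populationDecode <- function(spikes, preferences, interval = NULL,
                             period = NULL) {
  if (is(preferences, "OrientationMap")) {
    if (is.null(period)) period <- preferences@period
    preferences <- as.vector(preferences@theta)
  } else if (is.null(period)) period <- pi
  if (is.null(interval)) interval <- c(0, spikes@duration)
  stopifnot(interval[1] >= 0, interval[2] <= spikes@duration + 1e-9)
  ev <- spikes@events
  ev <- ev[ev$time >= interval[1] & ev$time <= interval[2] &
             ev$neuron <= length(preferences), , drop = FALSE]
  counts <- tabulate(ev$neuron, nbins = length(preferences))
  orientation <- isTRUE(all.equal(period, pi))
  thetaP <- if (orientation) 2 * preferences else preferences
  S <- sum(counts * sin(thetaP))
  C <- sum(counts * cos(thetaP))
  if (sum(counts) == 0 || (abs(S) < 1e-12 && abs(C) < 1e-12))
    return(new("DecodeResult", estimate = NA_real_, counts = counts,
               preferences = preferences, period = period, defined = FALSE))
  est <- atan2(S, C)
  est <- if (orientation) (est / 2) %% pi else est %% (2 * pi)
  new("DecodeResult", estimate = est * 180 / pi, counts = counts,
      preferences = preferences, period = period, defined = TRUE)
}

#' Sliding-window firing rates of the two LIP neurons
#'
#' @param spikes the LIP [SpikeData-class] (2 neurons; neuron 1 = left).
#' @param window window length, ms.
#' @param step window step, ms.
#' @return a [DecisionTrace-class] skeleton: window start times and the two
#'   rate series (decision fields unset; see [decideFromRates()]).
#' @export
lipRates <- function(spikes, window = 50, step = 10) {
  stopifnot(spikes@n == 2L)
  starts <- seq(0, spikes@duration - window, by = step)
  ev <- spikes@events
  rate <- function(id) {
    tt <- ev$time[ev$neuron == id]
    vapply(starts, function(s) sum(tt >= s & tt < s + window), 0) /
      (window / 1000)
  }
  new("DecisionTrace", times = starts, left = rate(1L), right = rate(2L),
      decision = "undecided", latency = NA_real_, window = window)
}

#' Decision and prevail latency from the two rate series
#'
#' The decision is the side with the higher total rate over the final
#' window; an exact tie is undecided. The latency is the earliest time after
#' which the winner's windowed rate is never below the loser's for the
#' remainder of the trial (the end of the period of uncertainty). Invariant
#' to joint rescaling of both series.
#'
#' @param trace a [DecisionTrace-class] from [lipRates()], or a list/data
#'   frame with fields times, left, right.
#' @return the completed [DecisionTrace-class].
#' @export
decideFromRates <- function(trace) {
  if (!is(trace, "DecisionTrace"))
    trace <- new("DecisionTrace", times = trace$times, left = trace$left,
                 right = trace$right, decision = "undecided",
                 latency = NA_real_,
                 window = if (!is.null(trace$window)) trace$window else 0)
  nf <- length(trace@times)
  lastL <- trace@left[nf]; lastR <- trace@right[nf]
  if (isTRUE(all.equal(lastL, lastR))) {
    trace@decision <- "undecided"
    trace@latency <- NA_real_
    return(trace)
  }
  win <- if (lastL > lastR) trace@left else trace@right
  lose <- if (lastL > lastR) trace@right else trace@left
  ok <- win >= lose
  # last index before which the winner was ever behind
  behind <- which(!ok)
  first <- if (length(behind)) max(behind) + 1L else 1L
  trace@decision <- if (lastL > lastR) "left" else "right"
  trace@latency <- if (first == 1L) 0 else trace@times[first]
  trace
}

#' Summarize an experiment table
#'
#' Per (displacement, side): accuracy and mean latency of correct trials;
#' plus the Spearman rank correlation between the per-magnitude mean latency
#' and the displacement magnitude (the harder the task, the longer the
#' period of uncertainty).
#'
#' @param results data.frame from [runExperiment()].
#' @return list with `byCondition` (data.frame), `byMagnitude` (data.frame),
#'   `spearmanRho` and overall `accuracy`.
#' @export
summarizeExperiment <- function(results) {
  key <- interaction(results$displacement, results$side, drop = TRUE)
  byCond <- do.call(rbind, lapply(split(results, key), function(d) {
    data.frame(displacement = d$displacement[1], side = d$side[1],
               n = nrow(d), accuracy = mean(d$correct),
               meanLatency = mean(d$latency[d$correct], na.rm = TRUE))
  }))
  byCond <- byCond[order(byCond$displacement, byCond$side), ]
  rownames(byCond) <- NULL
  byMag <- do.call(rbind, lapply(split(results, results$displacement),
    function(d) data.frame(displacement = d$displacement[1],
                           accuracy = mean(d$correct),
                           meanLatency = mean(d$latency[d$correct],
                                              na.rm = TRUE))))
  rownames(byMag) <- NULL
  rho <- if (nrow(byMag) > 2 && sum(is.finite(byMag$meanLatency)) > 2)
    suppressWarnings(cor(byMag$displacement, byMag$meanLatency,
                         method = "spearman",
                         use = "complete.obs")) else NA_real_
  list(byCondition = byCond, byMagnitude = byMag, spearmanRho = rho,
       accuracy = mean(results$correct))
}
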