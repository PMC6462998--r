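# Integrate-and-fire neuron models and the fixed-step simulation surface.
#
# Two models: a current-based LIF with exponential postsynaptic currents
# (hard reset, absolute refractory period), used everywhere except the LGN
# relay; and a conductance-based LIF whose spike triggers an
# after-hyperpolarizing potassium-like conductance instead of a hard reset,
# used for LGN relay cells. Both are integrated with the exact exponential
# per-step update; spikes are detected at step boundaries.

#' Parameters of the current-based LIF with exponential PSCs
#'
#' @param C_m membrane capacitance, pF.
#' @param tau_m membrane time constant, ms.
#' @param V_rest,V_th,V_reset resting, threshold and reset potentials, mV.
#' @param t_ref absolute refractory period, ms.
#' @param tau_syn_ex,tau_syn_in synaptic current time constants, ms.
#' @return named numeric vector of class "lifExpParams".
#' @export
lifExpParams <- function(C_m = 250, tau_m = 10, V_rest = -70, V_th = -55,
                         V_reset = -70, t_ref = 2, tau_syn_ex = 2,
                         tau_syn_in = 2) {
  stopifnot(V_reset < V_th, tau_m > 0, tau_syn_ex > 0, tau_syn_in > 0,
            t_ref >= 0, C_m > 0)
  structure(c(C_m = C_m, tau_m = tau_m, V_rest = V_rest, V_th = V_th,
              V_reset = V_reset, t_ref = t_ref, tau_syn_ex = tau_syn_ex,
              tau_syn_in = tau_syn_in),
            class = "lifExpParams")
}

#' Parameters of the conductance-based LIF with AHP conductance
#'
#' @param C_m membrane capacitance, pF.
#' @param g_L leak conductance, nS.
#' @param E_L,E_ex,E_in,E_ahp leak, excitatory, inhibitory and AHP reversal
#'   potentials, mV.
#' @param V_th spike threshold, mV (upward crossings emit spikes; there is no
#'   hard reset, refractoriness is mediated by the AHP conductance).
#' @param g_ahp AHP conductance increment per spike, nS.
#' @param tau_ahp AHP decay time constant, ms.
#' @param tau_syn_ex,tau_syn_in synaptic conductance time constants, ms.
#' @return named numeric vector of class "lifCondAhpParams".
#' @export
lifCondAhpParams <- function(C_m = 250, g_L = 20, E_L = -70, E_ex = 0,
                             E_in = -85, E_ahp = -90, V_th = -55, g_ahp = 60,
                             tau_ahp = 10, tau_syn_ex = 2, tau_syn_in = 2) {
  stopifnot(g_L > 0, g_ahp >= 0, E_in <= E_L, E_L < V_th, C_m > 0,
            tau_ahp > 0, tau_syn_ex > 0, tau_syn_in > 0)
  structure(c(C_m = C_m, g_L = g_L, E_L = E_L, E_ex = E_ex, E_in = E_in,
              E_ahp = E_ahp, V_th = V_th, g_ahp = g_ahp, tau_ahp = tau_ahp,
              tau_syn_ex = tau_syn_ex, tau_syn_in = tau_syn_in),
            class = "lifCondAhpParams")
}

# engine parameter row (13 columns, see src/engine.cpp)
.engineRow <- function(params) {
  if (inherits(params, "lifExpParams")) {
    c(params[["C_m"]], params[["tau_m"]], params[["V_rest"]],
      params[["V_th"]], params[["V_reset"]], params[["t_ref"]],
      params[["tau_syn_ex"]], params[["tau_syn_in"]], 0, 0, 0, 0, 1)
  } else if (inherits(params, "lifCondAhpParams")) {
    c(params[["C_m"]], params[["g_L"]], params[["E_L"]], params[["V_th"]],
      0, 0, params[["tau_syn_ex"]], params[["tau_syn_in"]],
      params[["E_ex"]], params[["E_in"]], params[["E_ahp"]],
      params[["g_ahp"]], params[["tau_ahp"]])
  } else stop("unknown neuron parameter class")
}

.modelCode <- function(params) if (inherits(params, "lifExpParams")) 0L else 1L

# injected current -> per-step vector
.injSteps <- function(injected, duration, dt) {
  n_steps <- as.integer(ceiling(duration / dt - 1e-9))
  if (is.null(injected)) return(numeric(0))
  if (is.numeric(injected) && length(injected) == 1)
    return(rep(injected, n_steps))
  if (is.data.frame(injected)) {
    stopifnot(all(c("time", "current") %in% names(injected)))
    if (is.unsorted(injected$time, strictly = TRUE))
      stop("injected current times must be strictly increasing")
    if (any(!is.finite(injected$current))) stop("NaN in injected current")
    tt <- (seq_len(n_steps) - 1) * dt
    idx <- findInterval(tt, injected$time)
    out <- numeric(n_steps)
    out[idx > 0] <- injected$current[idx[idx > 0]]
    return(out)
  }
  if (is.numeric(injected)) { # already per-step
    stopifnot(length(injected) >= n_steps)
    return(injected[seq_len(n_steps)])
  }
  stop("unsupported injected-current representation")
}

.arrivals <- function(spikesIn, dt) {
  if (is.null(spikesIn) || NROW(spikesIn) == 0)
    return(list(step = integer(0), w = numeric(0)))
  stopifnot(all(c("time", "weight") %in% names(spikesIn)))
  o <- order(spikesIn$time)
  list(step = as.integer(floor(spikesIn$time[o] / dt + 1e-9)),
       w = spikesIn$weight[o])
}

#' Simulate one current-based LIF neuron
#'
#' Exact exponential per-step update of
#' dV/dt = -(V - V_rest)/tau_m + (I_syn + I_inj)/C_m with exponentially
#' decaying synaptic currents. A threshold crossing emits a spike at the end
#' of the step and clamps V to V_reset for t_ref.
#'
#' @param params from [lifExpParams()].
#' @param injected injected current: a constant (pA), a data.frame
#'   (time, current) interpreted piecewise-constant, or a per-step vector.
#' @param spikesIn data.frame (time, weight); positive weights are excitatory
#'   current increments (pA), negative inhibitory.
#' @param duration ms.
#' @param dt step, ms (<= 0.5).
#' @return list with `spikes` (times, ms), `v` (voltage at each step end),
#'   `t` (step-end times), `dt`.
#' @export
simulateLifExp <- function(params, injected = 0, spikesIn = NULL,
                           duration = 1000, dt = 0.1) {
  stopifnot(inherits(params, "lifExpParams"), dt <= 0.5, dt > 0)
  inj <- .injSteps(injected, duration, dt)
  if (length(inj) && any(!is.finite(inj))) stop("NaN in injected current")
  a <- .arrivals(spikesIn, dt)
  r <- .cpp_simulate_neuron(0L, .engineRow(params), inj, a$step, a$w,
                            duration, dt)
  list(spikes = r$spikes, v = r$v, t = seq_along(r$v) * dt, dt = dt)
}

#' Simulate one conductance-based LIF neuron with AHP
#'
#' Conductance-based synapses g(t) (V - E_rev) and a spike-triggered AHP
#' conductance decaying with tau_ahp; spikes are upward threshold crossings
#' and there is no hard reset.
#'
#' @inheritParams simulateLifExp
#' @param params from [lifCondAhpParams()].
#' @param spikesIn data.frame (time, weight); positive weights increment the
#'   excitatory conductance (nS), negative the inhibitory conductance.
#' @return list as in [simulateLifExp()].
#' @export
simulateLifCondAhp <- function(params, injected = 0, spikesIn = NULL,
                               duration = 1000, dt = 0.1) {
  stopifnot(inherits(params, "lifCondAhpParams"), dt <= 0.5, dt > 0)
  inj <- .injSteps(injected, duration, dt)
  if (length(inj) && any(!is.finite(inj))) stop("NaN in injected current")
  a <- .arrivals(spikesIn, dt)
  r <- .cpp_simulate_neuron(1L, .engineRow(params), inj, a$step, a$w,
                            duration, dt)
  list(spikes = r$spikes, v = r$v, t = seq_along(r$v) * dt, dt = dt)
}

#' Closed-form interspike interval of the current-based LIF
#'
#' For a constant suprathreshold current I, the ISI is
#' t_ref + tau_m * log((V_inf - V_reset) / (V_inf - V_th)) with
#' V_inf = V_rest + I * tau_m / C_m. Returns Inf for subthreshold drive.
#'
#' @param params from [lifExpParams()].
#' @param I constant current, pA.
#' @return ISI in ms.
#' @export
lifExpISI <- function(params, I) {
  vinf <- params[["V_rest"]] + I * params[["tau_m"]] / params[["C_m"]]
  ifelse(vinf <= params[["V_th"]], Inf,
         params[["t_ref"]] + params[["tau_m"]] *
           log((vinf - params[["V_reset"]]) / (vinf - params[["V_th"]])))
}

#' Simulate an unconnected layer of neurons
#'
#' Runs N independent neurons of one model, each with its own injected
#' current, and collects the spikes. Deterministic given inputs.
#'
#' @param params from [lifExpParams()] or [lifCondAhpParams()] (shared by the
#'   layer).
#' @param injected matrix of currents, one row per neuron, one column per
#'   `tRes` ms (as produced by [filterFrames()]); or NULL.
#' @param duration ms.
#' @param dt step, ms.
#' @param tRes sampling of `injected`, ms.
#' @param label layer label for the output.
#' @param n number of neurons (defaults to nrow(injected)).
#' @return a [SpikeData-class].
#' @export
runLayer <- function(params, injected = NULL, duration = 600, dt = 0.1,
                     tRes = attr(injected, "tRes"), label = "layer",
                     n = nrow(injected)) {
  stopifnot(!is.null(n))
  if (is.null(tRes)) tRes <- 1
  model <- rep(.modelCode(params), n)
  pm <- matrix(rep(.engineRow(params), each = n), nrow = n)
  if (!is.null(injected)) {
    stopifnot(nrow(injected) == n)
    if (any(!is.finite(injected))) stop("NaN in injected current")
    nms <- as.integer(ceiling(duration))
    idx <- pmin(ncol(injected), floor((seq_len(nms) - 1) / tRes) + 1)
    injM <- injected[, idx, drop = FALSE]
    injRow <- seq_len(n) - 1L
  } else {
    injM <- matrix(0, 1, 1)
    injRow <- rep(-1L, n)
  }
  r <- .cpp_simulate_network(model, pm, integer(n + 1), integer(0),
                             numeric(0), integer(0), injRow, injM,
                             numeric(n), numeric(n), duration, dt,
                             integer(0))
  new("SpikeData", layer = label,
      events = data.frame(neuron = r$id, time = r$time), n = as.integer(n),
      duration = duration)
}
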