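# Network assembly and simulation: all layers and projections, flattened
# into the arrays the fixed-step engine consumes.
#
# Layers (label, size, neuron model):
#   LGN_ON/LGN_OFF   400 each, conductance-based relay cells
#   IN_ON/IN_OFF     400 each, current-based LIF
#   TRN_ON/TRN_OFF   400 each, current-based LIF
#   V1, MT           500 each (400 excitatory on 20x20 + 100 inhibitory
#                    on 10x10), current-based LIF
#   MSTe, MSTc       400 each, current-based LIF
#   LIP              2, current-based LIF

.layerTable <- function() {
  data.frame(
    label = c("LGN_ON", "LGN_OFF", "IN_ON", "IN_OFF", "TRN_ON", "TRN_OFF",
              "V1", "MT", "MSTe", "MSTc", "LIP"),
    n = c(400L, 400L, 400L, 400L, 400L, 400L, 500L, 500L, 400L, 400L, 2L),
    model = c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}

#' Default network configuration
#'
#' Nested list of every tunable parameter: integration step, map seeds,
#' retinal filter, neuron models, per-projection gains, MST template
#' geometry and background noise. Any entry can be overridden via
#' `override` (a nested list merged with [utils::modifyList()]).
#'
#' Free gain scalars default to values calibrated so that stimulation drives
#' the LGN near 20-60 Hz and keeps LIP rates in the 10-80 Hz range.
#'
#' @param override nested list of overrides.
#' @return the configuration list.
#' @export
networkConfig <- function(override = list()) {
  cfg <- list(
    dt = 0.1,
    delay = 1,
    prune = 1e-3,
    injClip = 900,
    adaptK = 50,
    layerSizes = list(grid = 20L, inhGrid = 10L, lip = 2L),
    seeds = list(v1Map = 11L, mtMap = 12L),
    maps = list(lambda = 10, nWaves = 30L, mirror = TRUE),
    retina = list(a_c = 1, a_s = 1, sigma_c = 0.3, sigma_s = 2.4,
                  tShape = c(2, 2), tScale = c(16, 32), tWeight = c(1, 0.7),
                  tSupport = 200, gain = 16000),
    neurons = list(lif = as.list(unclass(lifExpParams())),
                   lgn = as.list(unclass(lifCondAhpParams())),
                   lip = as.list(unclass(lifExpParams()))),
    gabor = list(ff_sigma_x = 3, ff_sigma_y = 2, lat_sigma = 1.5,
                 freq = 0.25, cutoff = 0.08, kappa = 1.2, sigma_lat = 3),
    mst = list(d = 0.15, tol = pi / 8, sigma_I = 2, sigma_ts = 3,
               focalXs = c(-5, 0, 5), sigma_fb = 2),
    gains = list(lgn_v1 = 17000, v1_e = 15, v1_i = 1000, fb_e = 1500,
                 fb_i = 2, k_c = 3000, mt_e = 15, mt_i = 1000,
                 mt_mst = 12000, mst_lat = 10, mst_lip_e = 200,
                 mst_lip_i = 4, lip_lip = 600),
    noise = list(rates = c(V1 = 1500, MT = 300, MSTe = 500, MSTc = 500,
                           LIP = 4500),
                 weight = 40),
    stimulus = list(sizePx = 600, frameInterval = 100 / 3, speed = 100,
                    dotRadiusPx = 4, duration = 600)
  )
  if (length(override)) cfg <- utils::modifyList(cfg, override)
  cfg
}

.rgcFromConfig <- function(config) {
  r <- config$retina
  rgcParams(a_c = r$a_c, a_s = r$a_s, sigma_c = r$sigma_c,
            sigma_s = r$sigma_s, tShape = r$tShape, tScale = r$tScale,
            tWeight = r$tWeight, tSupport = r$tSupport, gain = r$gain,
            gridDim = config$layerSizes$grid)
}

#' Assemble the full network
#'
#' Generates the V1 and MT pinwheel maps, builds every connection set, and
#' flattens everything into the engine arrays. Configurations violating the
#' fixed layer-size invariants are rejected.
#'
#' @param config from [networkConfig()].
#' @return a [Network-class].
#' @export
assembleNetwork <- function(config = networkConfig()) {
  if (config$layerSizes$grid != 20L)
    stop("layerSizes$grid: retinotopic layers must be 20 x 20")
  if (config$layerSizes$inhGrid != 10L)
    stop("layerSizes$inhGrid: cortical inhibitory populations must be 10 x 10")
  if (config$layerSizes$lip != 2L)
    stop("layerSizes$lip: LIP must have exactly 2 neurons")

  v1map <- generateMap(c(20L, 20L), lambda = config$maps$lambda,
                       nWaves = config$maps$nWaves,
                       seed = config$seeds$v1Map, period = pi,
                       mirror = config$maps$mirror)
  mtmap <- generateMap(c(20L, 20L), lambda = config$maps$lambda,
                       nWaves = config$maps$nWaves,
                       seed = config$seeds$mtMap, period = 2 * pi,
                       mirror = config$maps$mirror)

  g <- config$gains
  gb <- config$gabor
  mstP <- config$mst
  dl <- config$delay
  lgnv1 <- buildLgnV1(v1map, gain = g$lgn_v1, cutoff = gb$cutoff,
                      sigma_x = gb$ff_sigma_x, sigma_y = gb$ff_sigma_y,
                      freq = gb$freq, delay = dl)
  cs <- list(lgn_v1_on = lgnv1$on, lgn_v1_off = lgnv1$off,
             v1_lat = buildV1Lateral(v1map, g_e = g$v1_e, g_i = g$v1_i,
                                     sigma = gb$lat_sigma, freq = gb$freq,
                                     kappa = gb$kappa,
                                     sigma_lat = gb$sigma_lat,
                                     prune = config$prune, delay = dl,
                                     layer = "V1"),
             v1_mt = buildV1Mt(v1map, mtmap, k_c = g$k_c,
                               a_c = config$retina$a_c,
                               a_s = config$retina$a_s,
                               sigma_c = config$retina$sigma_c,
                               sigma_s = config$retina$sigma_s,
                               prune = config$prune, delay = dl),
             mt_lat = buildV1Lateral(mtmap, g_e = g$mt_e, g_i = g$mt_i,
                                     sigma = gb$lat_sigma, freq = gb$freq,
                                     kappa = gb$kappa,
                                     sigma_lat = gb$sigma_lat,
                                     prune = config$prune, delay = dl,
                                     layer = "MT"),
             mt_mste = buildMtMst(mtmap, "expansion", gain = g$mt_mst,
                                  d = mstP$d, tol = mstP$tol,
                                  sigma_I = mstP$sigma_I,
                                  focalXs = mstP$focalXs,
                                  prune = config$prune, delay = dl),
             mt_mstc = buildMtMst(mtmap, "contraction", gain = g$mt_mst,
                                  d = mstP$d, tol = mstP$tol,
                                  sigma_I = mstP$sigma_I,
                                  focalXs = mstP$focalXs,
                                  prune = config$prune, delay = dl))
  cs <- c(cs, buildMstLateral(gain = g$mst_lat, sigma_ts = mstP$sigma_ts,
                              focalXs = mstP$focalXs, prune = config$prune,
                              delay = dl)[c("ee", "cc", "ec", "ce")])
  lip <- buildMstLip(g_e = g$mst_lip_e, g_i = g$mst_lip_i,
                     g_lip = g$lip_lip, focalXs = mstP$focalXs, delay = dl)
  cs$mste_lip <- lip$e
  cs$mstc_lip <- lip$c
  cs$lip_lip <- lip$lip
  fb <- buildFeedbackInhibition(g_fb_e = g$fb_e, g_fb_i = g$fb_i,
                                sigma_fb = config$mst$sigma_fb,
                                delay = dl)
  cs <- c(cs, fb)

  layers <- .layerTable()
  layers$offset <- cumsum(c(0L, layers$n))[seq_len(nrow(layers))]
  engine <- .flattenEngine(layers, cs, config)
  new("Network", config = config, layers = layers,
      maps = list(v1 = v1map, mt = mtmap), connections = cs,
      engine = engine)
}

# flatten connection sets into CSR arrays for the engine
.flattenEngine <- function(layers, cs, config) {
  n <- sum(layers$n)
  off <- structure(layers$offset, names = layers$label)
  model <- rep(layers$model, layers$n)
  rowLif <- .engineRow(do.call(lifExpParams, config$neurons$lif))
  rowLgn <- .engineRow(do.call(lifCondAhpParams, config$neurons$lgn))
  rowLip <- .engineRow(do.call(lifExpParams, config$neurons$lip))
  params <- matrix(rep(rowLif, each = n), nrow = n)
  params[model == 1L, ] <- matrix(rep(rowLgn, each = sum(model == 1L)),
                                  nrow = sum(model == 1L))
  lipIdx <- off[["LIP"]] + seq_len(layers$n[layers$label == "LIP"])
  params[lipIdx, ] <- matrix(rep(rowLip, each = length(lipIdx)),
                             nrow = length(lipIdx))
  pre <- integer(0); post <- integer(0); w <- numeric(0); d <- numeric(0)
  for (x in cs) {
    s <- x@synapses
    if (!nrow(s)) next
    pre <- c(pre, off[[x@pre]] + s$pre - 1L)
    post <- c(post, off[[x@post]] + s$post - 1L)
    w <- c(w, s$weight)
    d <- c(d, s$delay)
  }
  o <- order(pre)
  pre <- pre[o]; post <- post[o]; w <- w[o]; d <- d[o]
  syn_ptr <- c(0L, cumsum(tabulate(pre + 1L, nbins = n)))
  delay_steps <- pmax(1L, as.integer(round(d / config$dt)))
  rates <- numeric(n); nw <- numeric(n)
  nwCfg <- config$noise$weight
  for (lbl in names(config$noise$rates)) {
    i <- which(layers$label == lbl)
    if (!length(i)) next
    idx <- off[[lbl]] + seq_len(layers$n[i])
    rates[idx] <- config$noise$rates[[lbl]]
    nw[idx] <- if (length(nwCfg) > 1) nwCfg[[lbl]] else nwCfg
  }
  list(n = n, model = model, params = params, syn_ptr = as.integer(syn_ptr),
       syn_post = as.integer(post), syn_w = w,
       syn_delay = as.integer(delay_steps), noise_rate = rates,
       noise_w = nw, offsets = off)
}

#' Census of an assembled network
#'
#' @param network a [Network-class].
#' @return list with `layers` (label, n, model) and `projections` (name,
#'   pre, post, synapse count).
#' @export
networkCensus <- function(network) {
  proj <- data.frame(
    name = names(network@connections),
    pre = vapply(network@connections, function(x) x@pre, ""),
    post = vapply(network@connections, function(x) x@post, ""),
    n_syn = vapply(network@connections, function(x) nrow(x@synapses), 0L),
    row.names = NULL)
  list(layers = network@layers[, c("label", "n", "model")],
       projections = proj)
}

#' Run the assembled network on a stimulus
#'
#' Retinal filtering of the frames produces ON and OFF currents that are
#' injected one-to-one into the LGN relay and IN cells of the matching
#' polarity channel; all layers are then advanced with the fixed-step engine.
#' Deterministic given the stimulus and the noise seed.
#'
#' @param network a [Network-class].
#' @param stimulus a [FrameSequence-class].
#' @param duration ms; must not exceed the stimulus length.
#' @param noiseSeed seed for the background Poisson noise.
#' @return a [SimulationResult-class] with one [SpikeData-class] per layer.
#' @export
runNetwork <- function(network, stimulus, duration = NULL, noiseSeed = 1L) {
  if (is.null(duration)) duration <- stimulusDuration(stimulus)
  if (duration > stimulusDuration(stimulus) + 1e-9)
    stop("duration exceeds the stimulus length")
  cfg <- network@config
  rgc <- .rgcFromConfig(cfg)
  on <- filterFrames(stimulus, rgc, "ON")
  offc <- filterFrames(stimulus, rgc, "OFF")
  # luminance adaptation and relay saturation, applied at injection: the
  # filter output is divided by (1 + adaptK * mean luminance) -- a Weber-like
  # gain control that equalizes sparse and dense stimuli -- and clipped so
  # extended bright regions cannot drive unphysiological currents
  adapt <- 1 / (1 + cfg$adaptK * mean(stimulus@frames))
  inj <- rbind(on, offc) * adapt
  inj <- pmin(pmax(inj, -cfg$injClip), cfg$injClip)
  eng <- network@engine
  injRow <- rep(-1L, eng$n)
  offs <- eng$offsets
  injRow[offs[["LGN_ON"]] + 1:400] <- 0:399
  injRow[offs[["IN_ON"]] + 1:400] <- 0:399
  injRow[offs[["LGN_OFF"]] + 1:400] <- 400:799
  injRow[offs[["IN_OFF"]] + 1:400] <- 400:799
  set.seed(noiseSeed)
  r <- .cpp_simulate_network(eng$model, eng$params, eng$syn_ptr,
                             eng$syn_post, eng$syn_w, eng$syn_delay,
                             injRow, inj, eng$noise_rate, eng$noise_w,
                             duration, cfg$dt, integer(0))
  # the engine simulates whole steps; expose the duration actually covered
  duration <- ceiling(duration / cfg$dt - 1e-9) * cfg$dt
  gid <- r$id
  spikes <- list()
  for (i in seq_len(nrow(network@layers))) {
    lbl <- network@layers$label[i]
    lo <- network@layers$offset[i]
    sel <- gid > lo & gid <= lo + network@layers$n[i]
    spikes[[lbl]] <- new("SpikeData", layer = lbl,
                         events = data.frame(neuron = gid[sel] - lo,
                                             time = r$time[sel]),
                         n = network@layers$n[i], duration = duration)
  }
  cfg$noiseSeed <- noiseSeed
  new("SimulationResult", spikes = spikes,
      stimulusMeta = stimulus@metadata, config = cfg, duration = duration)
}

#' Run the heading-decision experiment
#'
#' One trial per (displacement, side, trial index): generates the random-dot
#' stimulus with the expansion center displaced to the given side, runs the
#' network, and reduces the two LIP spike trains to a decision and a
#' latency.
#'
#' @param network a [Network-class].
#' @param displacements displacement magnitudes, px.
#' @param sides character vector from c("left", "right").
#' @param nTrials trials per condition.
#' @param duration ms.
#' @param baseSeed base for the per-trial stimulus and noise seeds.
#' @param window,step decision rate window and step, ms; the default decision
#'   window is longer than the 50 ms display window of [lipRates()] because
#'   with only two readout neurons a 50 ms count is too sparse for a stable
#'   prevail criterion.
#' @param verbose print one line per trial.
#' @return data.frame: displacement, side, trial, decision, correct,
#'   latency, nLeft, nRight (LIP spike counts).
#' @export
runExperiment <- function(network, displacements = displacementLevels(),
                          sides = c("left", "right"), nTrials = 3,
                          duration = 600, baseSeed = 1L, window = 200,
                          step = 20, verbose = FALSE) {
  cfg <- network@config$stimulus
  rows <- list()
  k <- 0L
  for (disp in displacements) for (side in sides) for (tr in seq_len(nTrials)) {
    k <- k + 1L
    seed <- baseSeed + 7919L * k
    sgn <- if (side == "left") -1 else 1
    stim <- makeDotStimulus(sgn * disp, duration = duration,
                            sizePx = cfg$sizePx, speed = cfg$speed,
                            dotRadiusPx = cfg$dotRadiusPx,
                            frameInterval = cfg$frameInterval, seed = seed)
    res <- runNetwork(network, stim, duration = duration,
                      noiseSeed = seed + 1L)
    tr8 <- lipRates(layerSpikes(res, "LIP"), window = window, step = step)
    dec <- decideFromRates(tr8)
    ev <- spikeEvents(res, "LIP")
    rows[[k]] <- data.frame(displacement = disp, side = side, trial = tr,
                            decision = dec@decision,
                            correct = identical(dec@decision, side),
                            latency = dec@latency,
                            nLeft = sum(ev$neuron == 1),
                            nRight = sum(ev$neuron == 2))
    if (verbose)
      message(sprintf("disp %3d %-5s trial %d: %s (latency %s ms)", disp,
                      side, tr, dec@decision, format(dec@latency)))
  }
  do.call(rbind, rows)
}
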