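# Connectivity builders: every projection of the model as an explicit
# weighted, delayed synapse list.
#
# Shared geometry: all retinotopic excitatory populations live on a 20 x 20
# lattice (grid units, origin at the center, y up); the 10 x 10 inhibitory
# populations of V1 and MT are dispersed among them on a spacing-2 lattice.
# V1 and MT are handled as single layers of 500 cells: ids 1..400 excitatory,
# 401..500 inhibitory.

#' Unsigned angular difference on the circle
#'
#' @param a,b angles, rad (vectorized).
#' @return difference folded to [0, pi].
#' @export
angularDifference <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# positions of a 400 + 100 cortical layer (exc rows first)
.corticalPositions <- function() {
  rbind(gridPositions(20L), gridPositions(10L, spacing = 2))
}

# preferences of a 500-cell cortical layer from its 20x20 map
.corticalPrefs <- function(map) {
  pos <- .corticalPositions()
  exc <- list(theta = as.vector(map@theta), phase = as.vector(map@phase))
  inh <- mapLookup(map, pos[401:500, , drop = FALSE])
  list(theta = c(exc$theta, inh$theta), phase = c(exc$phase, inh$phase),
       pos = pos, isExc = c(rep(TRUE, 400), rep(FALSE, 100)))
}

.connectionSet <- function(pre, post, df, prune = 0) {
  if (nrow(df) && prune > 0) {
    keep <- abs(df$weight) >= prune * max(abs(df$weight))
    df <- df[keep, , drop = FALSE]
  }
  df <- df[df$weight != 0, , drop = FALSE]
  rownames(df) <- NULL
  new("ConnectionSet", pre = pre, post = post, synapses = df)
}

#' Feedforward LGN -> V1 connectivity
#'
#' Every V1 cell owns an elongated Gabor receptive field (orientation and
#' phase from the shared pinwheel map). It receives an excitatory synapse
#' from each ON-channel LGN cell sitting on a positive lobe of the Gabor and
#' from each OFF-channel cell sitting on a negative lobe, with weight
#' proportional to |gabor| above a cutoff. Each cell's afferent weights are
#' normalized to a fixed total (`gain`), so responsiveness does not vary
#' with how many lattice cells its Gabor happens to cover.
#'
#' @param map the V1 [OrientationMap-class].
#' @param gain weight scale, pA per unit |gabor|.
#' @param cutoff minimum |gabor| (relative to the field peak of 1) for a
#'   synapse to exist.
#' @param sigma_x,sigma_y,freq Gabor geometry (grid units; elongated along
#'   the preferred orientation).
#' @param delay synaptic delay, ms.
#' @return list of two [ConnectionSet-class] objects, `on` (LGN_ON -> V1)
#'   and `off` (LGN_OFF -> V1); all weights are >= 0.
#' @export
buildLgnV1 <- function(map, gain = 30, cutoff = 0.2, sigma_x = 2,
                       sigma_y = 1, freq = 0.25, delay = 1) {
  pref <- .corticalPrefs(map)
  lgnPos <- gridPositions(20L)
  on <- list(); off <- list()
  for (i in seq_len(500)) {
    rf <- gaborRF(center = pref$pos[i, ], orientation = pref$theta[i],
                  phase = pref$phase[i], sigma_x = sigma_x,
                  sigma_y = sigma_y, freq = freq)
    g <- gabor(rf, lgnPos[, "x"], lgnPos[, "y"])
    g[abs(g) <= cutoff] <- 0
    tot <- sum(abs(g))
    if (tot > 0) g <- g / tot
    pos_ <- which(g > 0)
    neg_ <- which(g < 0)
    if (length(pos_))
      on[[length(on) + 1]] <- data.frame(pre = pos_, post = i,
                                         weight = gain * g[pos_],
                                         delay = delay)
    if (length(neg_))
      off[[length(off) + 1]] <- data.frame(pre = neg_, post = i,
                                           weight = gain * (-g[neg_]),
                                           delay = delay)
  }
  empty <- data.frame(pre = integer(0), post = integer(0),
                      weight = numeric(0), delay = numeric(0))
  list(on = .connectionSet("LGN_ON", "V1",
                           if (length(on)) do.call(rbind, on) else empty),
       off = .connectionSet("LGN_OFF", "V1",
                            if (length(off)) do.call(rbind, off) else empty))
}

#' Lateral connectivity within V1 (or MT)
#'
#' Excitatory cells connect with weight proportional to the positive Gabor
#' correlation between the two receptive fields (position, orientation and
#' phase all enter). Inhibitory cells connect preferentially onto cells with
#' a receptive-field phase difference around 180 degrees: a von Mises
#' weighting centered at pi, times the orientation similarity of the two
#' receptive fields and a Gaussian falloff with distance (push-pull
#' inhibition between matched-orientation, opposite-phase cells). The
#' lateral-connection Gabors are circular (sigma_x = sigma_y).
#'
#' @param map the layer's [OrientationMap-class].
#' @param g_e,g_i excitatory/inhibitory weight scales.
#' @param sigma circular Gabor envelope width, grid units.
#' @param freq Gabor carrier frequency, cycles per grid unit.
#' @param kappa von Mises concentration of the phase-difference weighting.
#' @param sigma_lat distance falloff of inhibitory connections, grid units.
#' @param prune drop |weight| below this fraction of the layer maximum.
#' @param delay synaptic delay, ms.
#' @param layer layer label.
#' @return a [ConnectionSet-class] (within-layer, no self-connections).
#' @export
buildV1Lateral <- function(map, g_e = 1, g_i = 4, sigma = 1.5, freq = 0.25,
                           kappa = 2, sigma_lat = 3, prune = 1e-3,
                           delay = 1, layer = "V1") {
  pref <- .corticalPrefs(map)
  n <- length(pref$theta)
  # circular Gabor fields on a common raster spanning the grid
  xs <- seq(-11, 11, by = 0.5)
  X <- rep(xs, times = length(xs)); Y <- rep(xs, each = length(xs))
  Gm <- matrix(0, n, length(X))
  for (i in seq_len(n)) {
    rf <- gaborRF(center = pref$pos[i, ], orientation = pref$theta[i],
                  phase = pref$phase[i], sigma_x = sigma, sigma_y = sigma,
                  freq = freq)
    Gm[i, ] <- gabor(rf, X, Y)
  }
  Gm <- Gm / sqrt(rowSums(Gm^2))
  C <- Gm %*% t(Gm)
  exc <- which(pref$isExc)
  inh <- which(!pref$isExc)
  # excitatory: positive correlation
  We <- pmax(C[exc, , drop = FALSE], 0) * g_e
  ePre <- rep(exc, times = n); ePost <- rep(seq_len(n), each = length(exc))
  eW <- as.vector(We)
  # inhibitory: von Mises around a phase difference of pi, orientation
  # similarity, Gaussian in space
  dphase <- outer(pref$phase[inh], pref$phase, "-")
  vm <- exp(kappa * cos(dphase - pi)) / exp(kappa)
  oriSim <- pmax(cos(2 * outer(pref$theta[inh], pref$theta, "-")), 0)
  d2 <- outer(pref$pos[inh, 1], pref$pos[, 1], "-")^2 +
        outer(pref$pos[inh, 2], pref$pos[, 2], "-")^2
  Wi <- -g_i * vm * oriSim * exp(-d2 / (2 * sigma_lat^2))
  iPre <- rep(inh, times = n); iPost <- rep(seq_len(n), each = length(inh))
  iW <- as.vector(Wi)
  df <- data.frame(pre = c(ePre, iPre), post = c(ePost, iPost),
                   weight = c(eW, iW), delay = delay)
  df <- df[df$pre != df$post, , drop = FALSE]
  .connectionSet(layer, layer, df, prune = prune)
}

#' Feedforward V1 -> MT connectivity
#'
#' w_ij = k_c * w_cs(dx, dy) * cos(phi_ij) when 0 <= phi_ij <= pi/2 and 0
#' otherwise, where w_cs is the difference-of-Gaussians factor of the MT
#' receptive field and phi_ij is the unsigned angle between the MT direction
#' preference and the V1 orientation preference (taken as a vector angle in
#' [0, pi)), folded to [0, pi].
#'
#' @param v1map,mtmap the two pinwheel maps (V1: period pi; MT: period 2*pi).
#' @param k_c amplification factor (> 0).
#' @param a_c,a_s,sigma_c,sigma_s DOG parameters of the MT receptive field,
#'   grid units.
#' @param prune drop weights below this fraction of the maximum.
#' @param delay synaptic delay, ms.
#' @return a [ConnectionSet-class] V1 -> MT; presynaptic cells are the 400
#'   V1 excitatory cells, targets all 500 MT cells.
#' @export
buildV1Mt <- function(v1map, mtmap, k_c = 1, a_c = 1, a_s = 0.9,
                      sigma_c = 0.8, sigma_s = 2.4, prune = 1e-3,
                      delay = 1) {
  if (k_c <= 0) stop("k_c must be positive")
  v1 <- .corticalPrefs(v1map)
  mt <- .corticalPrefs(mtmap)
  pre <- which(v1$isExc)
  dogP <- rgcParams(a_c = a_c, a_s = a_s, sigma_c = sigma_c,
                    sigma_s = sigma_s)
  dx <- outer(mt$pos[, 1], v1$pos[pre, 1], "-")
  dy <- outer(mt$pos[, 2], v1$pos[pre, 2], "-")
  wcs <- spatialDog(dogP, dx, dy)
  phi <- angularDifference(matrix(mt$theta, 500, length(pre)),
                           matrix(v1$theta[pre], 500, length(pre),
                                  byrow = TRUE))
  W <- ifelse(phi <= pi / 2, k_c * wcs * cos(phi), 0)
  df <- data.frame(pre = rep(pre, each = 500),
                   post = rep(seq_len(500), times = length(pre)),
                   weight = as.vector(W), delay = delay)
  .connectionSet("V1", "MT", df, prune = prune)
}

#' Construct an MST template specification
#'
#' @param kind "expansion" or "contraction".
#' @param focalX horizontal focal-point position, grid units (the vertical
#'   position is 0).
#' @param d template concentration, 1/grid-unit^2.
#' @param tol direction tolerance of the binary eligibility pattern, rad.
#' @param sigma_I MST on-center receptive-field width, grid units.
#' @param sigma_ts lateral template-similarity width, grid units.
#' @return an [MstTemplateSpec-class].
#' @export
mstTemplateSpec <- function(kind = "expansion", focalX = 0, d = 0.05,
                            tol = pi / 8, sigma_I = 2, sigma_ts = 3) {
  new("MstTemplateSpec", kind = kind, focal = c(focalX, 0), d = d, tol = tol,
      sigma_I = sigma_I, sigma_ts = sigma_ts)
}

#' MT -> MST template weight
#'
#' delta = atan2(y_e - y_MT, x_e - x_MT) is the angle from the MT cell to the
#' focal point. The binary pattern T is 1 only when the MT direction
#' preference lies within the tolerance of the radial direction away from
#' (expansion) or toward (contraction) the focal point. The weight is
#' T * exp(-d * r_focal^2) * exp(-r_mst^2 / (2 sigma_I^2)) / (2 pi sigma_I^2).
#' An MT cell exactly at the focal point has undefined radial direction and
#' gets weight 0.
#'
#' @param spec an [MstTemplateSpec-class].
#' @param mtPos matrix (x, y) of MT cell positions, grid units.
#' @param mtDir MT direction preferences, rad.
#' @param mstPos length-2 MST cell position, grid units.
#' @return numeric vector of weights, one per MT cell.
#' @export
mstTemplateWeight <- function(spec, mtPos, mtDir, mstPos) {
  mtPos <- matrix(mtPos, ncol = 2)
  fx <- spec@focal[1] - mtPos[, 1]
  fy <- spec@focal[2] - mtPos[, 2]
  r2f <- fx^2 + fy^2
  delta <- atan2(fy, fx)                    # MT cell -> focal point
  target <- if (spec@kind == "expansion") delta + pi else delta
  eligible <- angularDifference(mtDir, target) <= spec@tol & r2f > 1e-12
  r2m <- (mtPos[, 1] - mstPos[1])^2 + (mtPos[, 2] - mstPos[2])^2
  as.numeric(eligible) * exp(-spec@d * r2f) *
    exp(-r2m / (2 * spec@sigma_I^2)) / (2 * pi * spec@sigma_I^2)
}

#' Focal-point assignment of the MST cells
#'
#' Each of the 400 cells of an MST layer is assigned the focal point nearest
#' its own horizontal position; with the symmetric focal set the left/right
#' cell groups are mirror images.
#'
#' @param focalXs horizontal focal positions, grid units.
#' @return numeric vector (length 400) of assigned focal x per cell.
#' @export
mstFocalAssignment <- function(focalXs = c(-5, 0, 5)) {
  pos <- gridPositions(20L)
  # ties between two focal points go to the outer one, keeping the
  # assignment exactly mirror-symmetric
  d <- abs(outer(pos[, "x"], focalXs, "-")) -
    1e-9 * matrix(abs(focalXs), 400, length(focalXs), byrow = TRUE)
  focalXs[apply(d, 1, which.min)]
}

#' Feedforward MT -> MST connectivity
#'
#' Builds one expansion or contraction layer: each MST cell collects from the
#' MT excitatory cells selected by its template (see [mstTemplateWeight()]).
#'
#' @param mtmap the MT direction map (period 2*pi).
#' @param kind "expansion" or "contraction".
#' @param gain weight scale.
#' @param d,tol,sigma_I,sigma_ts template parameters, see
#'   [mstTemplateSpec()].
#' @param focalXs focal-point positions, grid units.
#' @param normalize scale each MST cell's afferent weights to a fixed total
#'   (`gain`), removing the map-sampling imbalance in how many eligible MT
#'   cells each template happens to find; FALSE keeps the raw template
#'   weights scaled by `gain`.
#' @param prune drop weights below this fraction of the maximum.
#' @param delay synaptic delay, ms.
#' @return a [ConnectionSet-class] MT -> MSTe or MSTc; all weights >= 0.
#' @export
buildMtMst <- function(mtmap, kind = "expansion", gain = 1, d = 0.05,
                       tol = pi / 8, sigma_I = 2, sigma_ts = 3,
                       focalXs = c(-5, 0, 5), normalize = TRUE,
                       prune = 1e-3, delay = 1) {
  mtPos <- gridPositions(20L)
  mtDir <- as.vector(mtmap@theta)
  mstPos <- gridPositions(20L)
  focal <- mstFocalAssignment(focalXs)
  out <- vector("list", 400)
  for (j in seq_len(400)) {
    spec <- mstTemplateSpec(kind = kind, focalX = focal[j], d = d, tol = tol,
                            sigma_I = sigma_I, sigma_ts = sigma_ts)
    w <- mstTemplateWeight(spec, mtPos, mtDir, mstPos[j, ])
    w <- if (normalize && sum(w) > 0) gain * w / sum(w) else gain * w
    nz <- which(w > 0)
    if (length(nz))
      out[[j]] <- data.frame(pre = nz, post = j, weight = w[nz],
                             delay = delay)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  empty <- data.frame(pre = integer(0), post = integer(0),
                      weight = numeric(0), delay = numeric(0))
  .connectionSet("MT", if (kind == "expansion") "MSTe" else "MSTc",
                 if (length(out)) do.call(rbind, out) else empty,
                 prune = prune)
}

#' Lateral connectivity within and between the MST layers
#'
#' Within a layer, cells sharing a focal point excite each other and cells
#' with different focal points inhibit each other, both with a Gaussian
#' falloff exp(-dpos^2 / (2 sigma_ts^2)). Between the expansion and
#' contraction layers every connection is inhibitory, with the position
#' Gaussian multiplied by a focal-similarity Gaussian
#' exp(-dfocal^2 / (2 sigma_ts^2)).
#'
#' @param gain weight scale.
#' @param sigma_ts similarity width, grid units.
#' @param focalXs focal-point positions, grid units.
#' @param prune drop |weights| below this fraction of the maximum.
#' @param delay synaptic delay, ms.
#' @return named list of four [ConnectionSet-class] objects: `ee` (within
#'   expansion), `cc` (within contraction), `ec` (expansion -> contraction),
#'   `ce` (contraction -> expansion).
#' @export
buildMstLateral <- function(gain = 1, sigma_ts = 3, focalXs = c(-5, 0, 5),
                            prune = 1e-3, delay = 1) {
  pos <- gridPositions(20L)
  focal <- mstFocalAssignment(focalXs)
  d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
  spat <- exp(-d2 / (2 * sigma_ts^2))
  same <- outer(focal, focal, "==")
  intra <- gain * ifelse(same, spat, -spat)
  diag(intra) <- 0
  df2 <- exp(-outer(focal, focal, "-")^2 / (2 * sigma_ts^2))
  inter <- -gain * spat * df2
  asDf <- function(W) {
    data.frame(pre = rep(seq_len(400), times = 400),
               post = rep(seq_len(400), each = 400),
               weight = as.vector(W), delay = delay)
  }
  list(ee = .connectionSet("MSTe", "MSTe", asDf(intra), prune = prune),
       cc = .connectionSet("MSTc", "MSTc", asDf(intra), prune = prune),
       ec = .connectionSet("MSTe", "MSTc", asDf(inter), prune = prune),
       ce = .connectionSet("MSTc", "MSTe", asDf(inter), prune = prune))
}

#' Decision readout: MST -> LIP and LIP mutual inhibition
#'
#' The left LIP neuron receives excitation from expansion cells whose focal
#' point is the left one and inhibition from every other MST cell (expansion
#' cells with other focal points and all contraction cells); symmetrically
#' for the right neuron. The two LIP neurons inhibit each other.
#'
#' @param g_e,g_i excitatory/inhibitory afferent weights.
#' @param g_lip mutual LIP inhibition weight.
#' @param focalXs focal-point positions; the most negative is "left", the
#'   most positive "right".
#' @param delay synaptic delay, ms.
#' @return named list of [ConnectionSet-class]: `e` (MSTe -> LIP), `c`
#'   (MSTc -> LIP), `lip` (LIP -> LIP). LIP neuron 1 = left, 2 = right.
#' @export
buildMstLip <- function(g_e = 1, g_i = 0.5, g_lip = 10,
                        focalXs = c(-5, 0, 5), delay = 1) {
  focal <- mstFocalAssignment(focalXs)
  leftX <- min(focalXs); rightX <- max(focalXs)
  wL <- ifelse(focal == leftX, g_e, -g_i)
  wR <- ifelse(focal == rightX, g_e, -g_i)
  e <- data.frame(pre = rep(seq_len(400), 2),
                  post = rep(c(1L, 2L), each = 400),
                  weight = c(wL, wR), delay = delay)
  c_ <- data.frame(pre = rep(seq_len(400), 2),
                   post = rep(c(1L, 2L), each = 400),
                   weight = rep(-g_i, 800), delay = delay)
  lip <- data.frame(pre = c(1L, 2L), post = c(2L, 1L),
                    weight = c(-g_lip, -g_lip), delay = delay)
  list(e = .connectionSet("MSTe", "LIP", e),
       c = .connectionSet("MSTc", "LIP", c_),
       lip = .connectionSet("LIP", "LIP", lip))
}

#' Feedback inhibition of the LGN relay via IN and TRN
#'
#' V1 excitatory cells drive the retinotopically aligned TRN and IN cells of
#' both polarity channels (excitatory, one-to-one plus a Gaussian
#' neighborhood of width `sigma_fb`), and TRN/IN cells inhibit their aligned
#' LGN relay cell (one-to-one). The pooled feedback acts as a gain control:
#' dense stimulation recruits broad V1 activity and damps the relay, sparse
#' stimulation passes through.
#'
#' @param g_fb_e V1 -> TRN/IN excitatory weight at zero offset (pA).
#' @param g_fb_i TRN/IN -> LGN inhibitory weight magnitude (nS).
#' @param sigma_fb pooling width of the V1 -> TRN/IN projection, grid units;
#'   0 gives strictly one-to-one feedback.
#' @param prune drop weights below this fraction of g_fb_e.
#' @param delay synaptic delay, ms.
#' @return named list of [ConnectionSet-class] objects; empty sets when a
#'   gain is zero.
#' @export
buildFeedbackInhibition <- function(g_fb_e = 20, g_fb_i = 1, sigma_fb = 2,
                                    prune = 0.05, delay = 1) {
  ids <- seq_len(400)
  pos <- gridPositions(20L)
  empty <- data.frame(pre = integer(0), post = integer(0),
                      weight = numeric(0), delay = numeric(0))
  pooled <- function(pre, post, w) {
    if (w == 0) return(.connectionSet(pre, post, empty))
    if (sigma_fb <= 0) {
      df <- data.frame(pre = ids, post = ids, weight = w, delay = delay)
      return(.connectionSet(pre, post, df))
    }
    d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
    W <- w * exp(-d2 / (2 * sigma_fb^2))
    W[W < prune * abs(w)] <- 0
    nz <- which(W != 0, arr.ind = TRUE)
    df <- data.frame(pre = nz[, 1], post = nz[, 2], weight = W[nz],
                     delay = delay)
    .connectionSet(pre, post, df)
  }
  one2one <- function(pre, post, w) {
    df <- if (w != 0)
      data.frame(pre = ids, post = ids, weight = w, delay = delay)
    else empty
    .connectionSet(pre, post, df)
  }
  list(v1_trn_on = pooled("V1", "TRN_ON", g_fb_e),
       v1_trn_off = pooled("V1", "TRN_OFF", g_fb_e),
       v1_in_on = pooled("V1", "IN_ON", g_fb_e),
       v1_in_off = pooled("V1", "IN_OFF", g_fb_e),
       trn_lgn_on = one2one("TRN_ON", "LGN_ON", -g_fb_i),
       trn_lgn_off = one2one("TRN_OFF", "LGN_OFF", -g_fb_i),
       in_lgn_on = one2one("IN_ON", "LGN_ON", -g_fb_i),
       in_lgn_off = one2one("IN_OFF", "LGN_OFF", -g_fb_i))
}
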