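# Retinal ganglion cell stage: a linear spatiotemporal filter turning
# luminance frames into injected currents for the ON and OFF channels.
#
# The spatial kernel is a difference of Gaussians with 1/sigma^2 prefactors,
#   w(r) = a_c exp(-r^2/sigma_c^2)/sigma_c^2 - a_s exp(-r^2/sigma_s^2)/sigma_s^2,
# evaluated in grid units of the 20 x 20 cell lattice spanning the image.
# The temporal kernel is the biphasic difference of two Gamma densities.
# The OFF channel uses the sign-inverted spatial kernel; currents are signed
# (no rectification before injection).

#' Construct retinal filter parameters
#'
#' @param a_c,a_s center and surround amplitudes.
#' @param sigma_c,sigma_s center and surround widths, grid units.
#' @param tShape,tScale,tWeight shapes, scales (ms) and sign weights of the
#'   two Gamma kernels; the difference must be biphasic.
#' @param tSupport temporal support, ms.
#' @param gain pA of injected current per unit filter response.
#' @param gridDim cells per side.
#' @return an [RGCParams-class].
#' @export
rgcParams <- function(a_c = 1, a_s = 1, sigma_c = 0.3, sigma_s = 2.4,
                      tShape = c(2, 2), tScale = c(16, 32),
                      tWeight = c(1, 0.7), tSupport = 200, gain = 1500,
                      gridDim = 20L) {
  new("RGCParams", a_c = a_c, a_s = a_s, sigma_c = sigma_c, sigma_s = sigma_s,
      tShape = tShape, tScale = tScale, tWeight = tWeight,
      tSupport = tSupport, gain = gain, gridDim = as.integer(gridDim))
}

#' Spatial difference-of-Gaussians weight
#'
#' @param params an [RGCParams-class].
#' @param dx,dy offsets from the cell center, grid units (vectorized).
#' @return kernel value(s).
#' @export
spatialDog <- function(params, dx, dy) {
  r2 <- dx^2 + dy^2
  params@a_c * exp(-r2 / params@sigma_c^2) / params@sigma_c^2 -
    params@a_s * exp(-r2 / params@sigma_s^2) / params@sigma_s^2
}

#' Biphasic temporal kernel
#'
#' Difference of two Gamma probability densities, truncated to the support
#' window.
#'
#' @param params an [RGCParams-class].
#' @param t time(s) since stimulus, ms; must be >= 0.
#' @return kernel value(s), 1/ms.
#' @export
temporalKernel <- function(params, t) {
  stopifnot(all(t >= 0))
  v <- params@tWeight[1] * dgamma(t, shape = params@tShape[1],
                                  scale = params@tScale[1]) -
       params@tWeight[2] * dgamma(t, shape = params@tShape[2],
                                  scale = params@tScale[2])
  v[t > params@tSupport] <- 0
  v
}

#' Positions of a square neuron lattice
#'
#' Cell centers in grid units, centered on the origin, y upward. Neuron ids
#' run down columns (column-major), matching R's matrix layout.
#'
#' @param G cells per side.
#' @param spacing lattice spacing, grid units.
#' @return matrix with columns x, y and one row per neuron.
#' @export
gridPositions <- function(G, spacing = 1) {
  r <- rep(1:G, times = G)
  c <- rep(1:G, each = G)
  cbind(x = (c - (G + 1) / 2) * spacing, y = ((G + 1) / 2 - r) * spacing)
}

# Block-average a frame stack down to an internal raster (res cells per grid
# unit). Falls back to pixel-center sampling when the sizes do not divide.
.downsampleFrames <- function(frames, G, res = 3L) {
  nf <- dim(frames)[1]; px <- dim(frames)[2]
  rn <- G * res
  out <- array(0, dim = c(nf, rn, rn))
  if (px %% rn == 0) {
    b <- px %/% rn
    for (f in seq_len(nf)) {
      m <- frames[f, , ]
      m <- matrix(colMeans(matrix(m, nrow = b)), nrow = px %/% b, byrow = FALSE)
      m <- t(matrix(colMeans(matrix(t(m), nrow = b)), nrow = px %/% b))
      out[f, , ] <- m
    }
  } else {
    idx <- pmin(px, pmax(1L, round((seq_len(rn) - 0.5) * px / rn + 0.5)))
    for (f in seq_len(nf)) out[f, , ] <- frames[f, idx, idx]
  }
  out
}

#' Filter a frame sequence into per-cell injected currents
#'
#' Convolves the stimulus with the spatiotemporal receptive field of every
#' cell on the lattice: per cell, response(t) = gain * sum_tau h(tau) *
#' [spatial (x) frame](t - tau), with the spatial kernel integrated over an
#' internal raster and the temporal convolution sampled at 1 ms. The OFF
#' polarity inverts the sign of the spatial kernel. History before stimulus
#' onset is zero-padded (with a warning when the stimulus is shorter than the
#' temporal support).
#'
#' @param frames a [FrameSequence-class].
#' @param params an [RGCParams-class]; the lattice spans the full image.
#' @param polarity "ON" or "OFF".
#' @param tRes temporal sampling of the output currents, ms.
#' @param res internal raster resolution, cells per grid unit (the spatial
#'   kernel is integrated over this raster).
#' @return matrix of currents (pA), one row per cell (column-major lattice
#'   order), one column per `tRes` ms; attribute `tRes` records the sampling.
#' @export
filterFrames <- function(frames, params, polarity = c("ON", "OFF"),
                         tRes = 1, res = 6L) {
  polarity <- match.arg(polarity)
  G <- params@gridDim
  px <- dim(frames@frames)[2]
  if (px < G) stop("lattice does not fit inside the image")
  dur <- stimulusDuration(frames)
  if (dur < params@tSupport)
    warning("stimulus shorter than the temporal support; history zero-padded")
  ds <- .downsampleFrames(frames@frames, G, res)
  rn <- G * res
  # raster cell centers in grid units (grid spans the image: 1 unit = px/G px)
  rx <- ((1:rn) - 0.5) / res - G / 2
  ry <- G / 2 - ((1:rn) - 0.5) / res
  gp <- gridPositions(G)
  K <- matrix(0, G * G, rn * rn)
  RX <- matrix(rx, rn, rn, byrow = TRUE)
  RY <- matrix(ry, rn, rn)
  cellArea <- (1 / res)^2
  for (i in seq_len(G * G))
    K[i, ] <- spatialDog(params, as.vector(RX) - gp[i, "x"],
                         as.vector(RY) - gp[i, "y"]) * cellArea
  if (polarity == "OFF") K <- -K
  nf <- dim(ds)[1]
  S <- K %*% t(matrix(ds, nrow = nf))        # cells x frames
  # expand to tRes sampling and convolve with the temporal kernel
  nT <- as.integer(ceiling(dur / tRes - 1e-9))
  fIdx <- pmin(nf, floor((seq_len(nT) - 1) * tRes / frames@frameInterval) + 1)
  Sm <- S[, fIdx, drop = FALSE]
  taps <- seq(0, params@tSupport, by = tRes)
  h <- temporalKernel(params, taps) * tRes
  out <- matrix(0, G * G, nT)
  for (k in seq_along(h)) {
    lag <- k - 1
    if (lag >= nT) break
    if (h[k] == 0) next
    out[, (lag + 1):nT] <- out[, (lag + 1):nT] +
      h[k] * Sm[, 1:(nT - lag), drop = FALSE]
  }
  out <- params@gain * out
  attr(out, "tRes") <- tRes
  out
}

#' Export currents as a delimited table
#'
#' @param currents matrix from [filterFrames()].
#' @param file path; tab-separated columns neuron_id, t_ms, pA.
#' @return invisibly, the data.frame written.
#' @export
writeCurrents <- function(currents, file) {
  tRes <- attr(currents, "tRes")
  df <- data.frame(neuron_id = rep(seq_len(nrow(currents)), ncol(currents)),
                   t_ms = rep((seq_len(ncol(currents)) - 1) * tRes,
                              each = nrow(currents)),
                   pA = as.vector(currents))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
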