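# Pinwheel preference maps and Gabor receptive fields.
#
# Maps are generated by superposing random complex plane waves of a single
# wavenumber 2*pi/lambda; the argument of the superposed field, mapped onto
# the period, produces the pinwheel layout of orientation (period pi) or
# direction (period 2*pi) preferences. The receptive-field phase map is a
# second, independent realization.

#' Generate a pinwheel-structured preference map
#'
#' @param dims grid dimensions (rows, cols).
#' @param lambda generating wavelength, grid units.
#' @param nWaves number of superposed plane waves.
#' @param seed RNG seed.
#' @param period pi for orientation maps, 2*pi for direction maps.
#' @param mirror make the map mirror-symmetric about the vertical midline
#'   (right half = reflected left half, angles reflected as theta -> pi -
#'   theta and phases negated), so downstream left/right decision circuitry
#'   is structurally unbiased.
#' @return an [OrientationMap-class]; the same seed and parameters always
#'   yield the identical map.
#' @export
generateMap <- function(dims = c(20L, 20L), lambda = 10, nWaves = 30L,
                        seed = 1L, period = pi, mirror = FALSE) {
  stopifnot(lambda > 0, nWaves >= 1)
  set.seed(seed)
  G <- as.integer(dims)
  pos <- expand.grid(r = seq_len(G[1]), c = seq_len(G[2]))
  x <- pos$c - (G[2] + 1) / 2
  y <- (G[1] + 1) / 2 - pos$r
  k <- 2 * pi / lambda
  field <- function() {
    alpha <- runif(nWaves, 0, 2 * pi)
    phi <- runif(nWaves, 0, 2 * pi)
    z <- complex(length.out = length(x), real = 0, imaginary = 0)
    for (j in seq_len(nWaves))
      z <- z + exp(1i * (k * (cos(alpha[j]) * x + sin(alpha[j]) * y) + phi[j]))
    z
  }
  z1 <- field()
  z2 <- field()
  arg1 <- Arg(z1) %% (2 * pi)
  theta <- if (isTRUE(all.equal(period, pi))) arg1 / 2 else arg1
  phase <- Arg(z2) %% (2 * pi)
  theta <- matrix(theta, G[1], G[2])
  phase <- matrix(phase, G[1], G[2])
  if (mirror) {
    half <- G[2] %/% 2
    src <- half:1
    dst <- (G[2] - half + 1):G[2]
    theta[, dst] <- (pi - theta[, src]) %% period
    phase[, dst] <- (2 * pi - phase[, src]) %% (2 * pi)
  }
  new("OrientationMap", dims = G, theta = theta, phase = phase,
      lambda = lambda, period = period, seed = as.integer(seed))
}

#' Construct a Gabor receptive field
#'
#' @param center length-2 position, grid units.
#' @param orientation rad.
#' @param phase rad.
#' @param sigma_x envelope width along the orientation, grid units.
#' @param sigma_y envelope width across the orientation, grid units.
#' @param freq carrier frequency, cycles per grid unit (carrier runs across
#'   the orientation).
#' @return a [GaborRF-class].
#' @export
gaborRF <- function(center = c(0, 0), orientation = 0, phase = 0,
                    sigma_x = 1.5, sigma_y = 1.5, freq = 0.25) {
  new("GaborRF", center = center, orientation = orientation, phase = phase,
      sigma_x = sigma_x, sigma_y = sigma_y, freq = freq)
}

#' Evaluate a Gabor receptive field
#'
#' Oriented Gaussian envelope times a cosine carrier perpendicular to the
#' orientation: at the center with phase 0 the value is the envelope peak.
#'
#' @param rf a [GaborRF-class].
#' @param x,y evaluation points, grid units (vectorized).
#' @return field value(s).
#' @export
gabor <- function(rf, x, y) {
  dx <- x - rf@center[1]
  dy <- y - rf@center[2]
  xr <- cos(rf@orientation) * dx + sin(rf@orientation) * dy
  yr <- -sin(rf@orientation) * dx + cos(rf@orientation) * dy
  exp(-xr^2 / (2 * rf@sigma_x^2) - yr^2 / (2 * rf@sigma_y^2)) *
    cos(2 * pi * rf@freq * yr + rf@phase)
}

# evaluate a set of GaborRFs on a common raster -> matrix (cells x points)
.gaborFields <- function(rfs, rasterX, rasterY) {
  m <- matrix(0, length(rfs), length(rasterX))
  for (i in seq_along(rfs)) m[i, ] <- gabor(rfs[[i]], rasterX, rasterY)
  m
}

#' Correlation of two Gabor receptive fields
#'
#' Normalized inner product of the two fields on a common raster covering
#' both envelopes; symmetric, in [-1, 1], and 1 for identical fields.
#'
#' @param a,b [GaborRF-class] objects.
#' @param res raster resolution, points per grid unit.
#' @return scalar in [-1, 1].
#' @export
gaborCorrelation <- function(a, b, res = 4) {
  pad <- 4 * max(a@sigma_x, a@sigma_y, b@sigma_x, b@sigma_y)
  xr <- range(a@center[1], b@center[1]) + c(-pad, pad)
  yr <- range(a@center[2], b@center[2]) + c(-pad, pad)
  xs <- seq(xr[1], xr[2], by = 1 / res)
  ys <- seq(yr[1], yr[2], by = 1 / res)
  X <- rep(xs, times = length(ys))
  Y <- rep(ys, each = length(xs))
  fa <- gabor(a, X, Y)
  fb <- gabor(b, X, Y)
  den <- sqrt(sum(fa^2) * sum(fb^2))
  if (den == 0) return(0)
  sum(fa * fb) / den
}

#' Map values at arbitrary positions
#'
#' Samples a preference map at positions in grid units (nearest grid cell);
#' used to give the dispersed inhibitory cells preferences from the shared
#' map.
#'
#' @param map an [OrientationMap-class].
#' @param pos matrix with columns x, y, grid units (origin at grid center).
#' @return list with vectors `theta` and `phase`.
#' @export
mapLookup <- function(map, pos) {
  G <- map@dims
  c_ <- pmin(G[2], pmax(1, round(pos[, 1] + (G[2] + 1) / 2)))
  r_ <- pmin(G[1], pmax(1, round((G[1] + 1) / 2 - pos[, 2])))
  idx <- cbind(r_, c_)
  list(theta = map@theta[idx], phase = map@phase[idx])
}

#' Save / load a preference map as delimited text
#'
#' Writes two tab-separated grids (theta, phase) with a small key:value
#' header sidecar.
#'
#' @param map an [OrientationMap-class].
#' @param file base path; writes `<file>_theta.tsv`, `<file>_phase.tsv` and
#'   `<file>_meta.txt`.
#' @return invisibly, the paths written.
#' @export
writeMap <- function(map, file) {
  p <- paste0(file, c("_theta.tsv", "_phase.tsv", "_meta.txt"))
  write.table(map@theta, p[1], sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(map@phase, p[2], sep = "\t", row.names = FALSE, col.names = FALSE)
  writeLines(c(paste("dims:", paste(map@dims, collapse = " ")),
               paste("lambda:", map@lambda),
               paste("period:", map@period),
               paste("seed:", map@seed)), p[3])
  invisible(p)
}

#' @rdname writeMap
#' @export
readMap <- function(file) {
  meta <- readLines(paste0(file, "_meta.txt"))
  val <- function(key) sub(paste0("^", key, ": *"), "",
                           grep(paste0("^", key, ":"), meta, value = TRUE))
  dims <- as.integer(strsplit(val("dims"), " ")[[1]])
  new("OrientationMap", dims = dims,
      theta = as.matrix(read.table(paste0(file, "_theta.tsv"), sep = "\t")),
      phase = as.matrix(read.table(paste0(file, "_phase.tsv"), sep = "\t")),
      lambda = as.numeric(val("lambda")), period = as.numeric(val("period")),
      seed = as.integer(val("seed")))
}
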