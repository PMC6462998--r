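# Random-dot kinematogram with a displaced focus of expansion.
#
# Coordinates are px with origin at the screen center, x rightward, y upward.
# The field holds 50 dots: 36 move radially away from the expansion center
# (pure expansion) and 14 carry fixed random directions. Each dot lives for
# 100 ms and is then re-positioned uniformly at random, keeping its motion
# direction (radial dots have it recomputed from the center so the expansion
# subfield stays consistent). Ages are staggered uniformly at start, so with
# the default frame interval of one third of the lifetime about one third of
# the dots is renewed on every frame.

#' Default pixel scale
#'
#' Fixed by the stimulus geometry: 20 px corresponds to 0.67 degrees of
#' visual angle.
#' @return pixels per degree.
#' @export
defaultPxPerDegree <- function() 20 / 0.67

#' The seven expansion-center displacement magnitudes (px)
#'
#' 20 to 140 px in steps of 20, i.e. 0.67 to 4.67 degrees at the fixed pixel
#' scale.
#' @return integer vector of length 7.
#' @export
displacementLevels <- function() seq(20L, 140L, by = 20L)

#' Initialize the random-dot flow field
#'
#' Places 50 dots uniformly on the screen; 36 get radial directions pointing
#' away from the expansion center, 14 get uniform random directions. Ages are
#' staggered uniformly over the lifetime so renewal is spread across frames.
#'
#' @param displacementPx signed horizontal displacement of the expansion
#'   center from the screen center (negative = left), px.
#' @param sizePx screen side length, px.
#' @param speed dot speed, px/s.
#' @param seed RNG seed; if NULL the current RNG state is used.
#' @param nDots,nRadial dot counts (defaults 50 and 36).
#' @param lifetime dot lifetime, ms.
#' @return a [DotField-class].
#' @export
initDotField <- function(displacementPx, sizePx = 600, speed = 100,
                         seed = NULL, nDots = 50L, nRadial = 36L,
                         lifetime = 100) {
  if (abs(displacementPx) >= sizePx / 2)
    stop("displacement places the expansion center off-screen")
  if (!is.null(seed)) set.seed(seed)
  half <- sizePx / 2
  pos <- cbind(runif(nDots, -half, half), runif(nDots, -half, half))
  isRadial <- c(rep(TRUE, nRadial), rep(FALSE, nDots - nRadial))
  center <- c(displacementPx, 0)
  dirs <- matrix(0, nDots, 2)
  dirs[isRadial, ] <- .radialDirections(pos[isRadial, , drop = FALSE], center)
  ang <- runif(nDots - nRadial, 0, 2 * pi)
  dirs[!isRadial, ] <- cbind(cos(ang), sin(ang))
  ages <- runif(nDots, 0, lifetime)
  new("DotField", positions = pos, directions = dirs, ages = ages,
      isRadial = isRadial, center = center, speed = speed, sizePx = sizePx,
      lifetime = lifetime)
}

.radialDirections <- function(pos, center) {
  rel <- cbind(pos[, 1] - center[1], pos[, 2] - center[2])
  r <- sqrt(rowSums(rel^2))
  deg <- r < 1e-9
  if (any(deg)) { # dot exactly at the center: arbitrary rightward
    rel[deg, 1] <- 1; rel[deg, 2] <- 0; r[deg] <- 1
  }
  rel / r
}

#' Advance the dot field by one frame
#'
#' Moves every dot along its direction, ages it, and renews dots whose age
#' exceeds the lifetime: renewed dots are re-positioned uniformly at random
#' with age reset to age mod lifetime; random-class dots keep their direction
#' verbatim while radial dots get it recomputed from the expansion center.
#' Dots that leave the screen are re-positioned the same way.
#'
#' @param field a [DotField-class].
#' @param dtFrame frame interval, ms (0 leaves the field unchanged).
#' @return list with elements `field` (the advanced DotField) and `renewed`
#'   (logical vector marking dots that were re-positioned).
#' @export
stepDots <- function(field, dtFrame) {
  stopifnot(dtFrame >= 0)
  if (dtFrame == 0) {
    return(list(field = field, renewed = rep(FALSE, nrow(field@positions))))
  }
  pos <- field@positions + field@directions * field@speed * dtFrame / 1000
  ages <- field@ages + dtFrame
  half <- field@sizePx / 2
  expired <- ages >= field@lifetime
  off <- pos[, 1] < -half | pos[, 1] > half | pos[, 2] < -half | pos[, 2] > half
  renew <- expired | off
  n <- sum(renew)
  if (n) {
    pos[renew, ] <- cbind(runif(n, -half, half), runif(n, -half, half))
    rr <- renew & field@isRadial
    if (any(rr))
      field@directions[rr, ] <- .radialDirections(pos[rr, , drop = FALSE],
                                                  field@center)
  }
  ages[expired] <- ages[expired] %% field@lifetime
  # re-positioned-off-screen dots keep their age (not a lifetime event)
  field@positions <- pos
  field@ages <- ages
  list(field = field, renewed = renew)
}

#' Render a dot-field trace into luminance frames
#'
#' Bright anti-aliased discs on a dark background; pixel coverage falls off
#' linearly over one pixel at the disc edge.
#'
#' @param trace list of [DotField-class] states, one per frame.
#' @param sizePx screen side length, px.
#' @param dotRadiusPx disc radius, px.
#' @param frameInterval ms per frame.
#' @param metadata extra metadata entries to record.
#' @return a [FrameSequence-class].
#' @export
renderDots <- function(trace, sizePx = 600, dotRadiusPx = 4,
                       frameInterval = 100 / 3, metadata = list()) {
  nf <- length(trace)
  frames <- array(0, dim = c(nf, sizePx, sizePx))
  half <- sizePx / 2
  for (f in seq_len(nf)) {
    fr <- matrix(0, sizePx, sizePx)
    pos <- trace[[f]]@positions
    for (k in seq_len(nrow(pos))) {
      # pixel (row i, col j) center: x = j - 0.5 - half, y = half - i + 0.5
      cx <- pos[k, 1] + half + 0.5
      cy <- half - pos[k, 2] + 0.5
      j0 <- max(1L, floor(cx - dotRadiusPx - 1)); j1 <- min(sizePx, ceiling(cx + dotRadiusPx + 1))
      i0 <- max(1L, floor(cy - dotRadiusPx - 1)); i1 <- min(sizePx, ceiling(cy + dotRadiusPx + 1))
      if (j0 > j1 || i0 > i1) next
      jj <- j0:j1; ii <- i0:i1
      d <- sqrt(outer((ii - cy)^2, (jj - cx)^2, `+`))
      cov <- pmin(pmax(dotRadiusPx + 0.5 - d, 0), 1)
      fr[ii, jj] <- pmax(fr[ii, jj], cov)
    }
    frames[f, , ] <- fr
  }
  md <- c(list(kind = "dots", frameInterval = frameInterval,
               nDots = nrow(trace[[1]]@positions),
               nRadial = sum(trace[[1]]@isRadial),
               center = trace[[1]]@center,
               displacementPx = trace[[1]]@center[1],
               side = if (trace[[1]]@center[1] < 0) "left"
                      else if (trace[[1]]@center[1] > 0) "right" else "center",
               speed = trace[[1]]@speed, dotRadiusPx = dotRadiusPx),
          metadata)
  new("FrameSequence", frames = frames, frameInterval = frameInterval,
      pxPerDegree = defaultPxPerDegree(), metadata = md)
}

#' Generate a complete random-dot optic-flow stimulus
#'
#' Convenience wrapper: seeds the RNG, initializes the field, advances it
#' frame by frame and renders the frames.
#'
#' @inheritParams initDotField
#' @param duration ms.
#' @param frameInterval ms per frame.
#' @param dotRadiusPx disc radius, px.
#' @return a [FrameSequence-class]; metadata records the seed, displacement
#'   and true side.
#' @export
makeDotStimulus <- function(displacementPx, duration = 600, sizePx = 600,
                            speed = 100, dotRadiusPx = 4,
                            frameInterval = 100 / 3, seed = 1L) {
  nf <- ceiling(duration / frameInterval - 1e-9)
  field <- initDotField(displacementPx, sizePx = sizePx, speed = speed,
                        seed = seed)
  trace <- vector("list", nf)
  trace[[1]] <- field
  if (nf > 1) for (f in 2:nf) {
    field <- stepDots(field, frameInterval)$field
    trace[[f]] <- field
  }
  renderDots(trace, sizePx = sizePx, dotRadiusPx = dotRadiusPx,
             frameInterval = frameInterval, metadata = list(seed = seed))
}
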