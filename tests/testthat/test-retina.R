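# Spatiotemporal retinal filter.

test_that("spatial DOG matches its closed form at the origin and is radial", {
  p <- rgcParams(a_c = 1, a_s = 0.7, sigma_c = 0.8, sigma_s = 2.4)
  expect_equal(spatialDog(p, 0, 0), 1 / 0.8^2 - 0.7 / 2.4^2)
  expect_equal(spatialDog(p, 3, 4), spatialDog(p, 5, 0))
  expect_equal(spatialDog(p, -2, 1), spatialDog(p, 2, -1))
})

test_that("fine-grid integral of the DOG approaches pi * (a_c - a_s)", {
  # Gaussian integral oracle: integral of exp(-r^2/s^2)/s^2 over the plane = pi
  p <- rgcParams(a_c = 1, a_s = 0.6, sigma_c = 0.5, sigma_s = 1.5)
  g <- seq(-12, 12, by = 0.05)
  v <- sum(spatialDog(p, rep(g, times = length(g)),
                      rep(g, each = length(g)))) * 0.05^2
  expect_equal(v, pi * (1 - 0.6), tolerance = 1e-3)
})

test_that("invalid kernel widths are rejected at construction", {
  expect_error(rgcParams(sigma_c = -1), "sigma")
  expect_error(rgcParams(sigma_c = 2, sigma_s = 1), "sigma")
})

test_that("temporal kernel is zero at t = 0 and biphasic", {
  p <- rgcParams()
  expect_equal(temporalKernel(p, 0), 0)
  tt <- seq(0.5, p@tSupport, by = 0.5)
  v <- temporalKernel(p, tt)
  s <- sign(v[abs(v) > 1e-12])
  expect_equal(sum(diff(s) != 0), 1L)   # exactly one sign change
  expect_error(rgcParams(tWeight = c(1, 1), tScale = c(16, 16)),
               "biphasic")
})

test_that("a monophasic kernel variant evaluates as a single Gamma density", {
  p <- rgcParams(tWeight = c(1, 0))
  expect_true(all(temporalKernel(p, seq(1, 200, 5)) > 0))
  expect_equal(temporalKernel(p, 16),
               dgamma(16, shape = 2, scale = 16), tolerance = 1e-6)
})

test_that("all-zero frames produce all-zero currents", {
  cur <- filterFrames(zeroFrames(), rgcParams(gain = 1000), "ON")
  expect_true(all(cur == 0))
  expect_equal(nrow(cur), 400L)
})

test_that("the filter is linear and ON/OFF antisymmetric", {
  fr <- discFrames()
  p <- rgcParams(gain = 500)
  suppressWarnings({
    on1 <- filterFrames(fr, p, "ON")
    fr2 <- fr; fr2@frames <- fr@frames * 0.5
    on2 <- filterFrames(fr2, p, "ON")
    off1 <- filterFrames(fr, p, "OFF")
  })
  expect_equal(on2, on1 * 0.5, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(off1, -on1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("filter response agrees with a direct convolution oracle", {
  fr <- discFrames()
  p <- rgcParams(gain = 500)
  suppressWarnings(cur <- filterFrames(fr, p, "ON"))
  ctr <- 190L  # central lattice cell (column-major 20x20: r=10, c=10)
  # oracle: spatial response of the disc at the center cell, integrated on
  # the same raster, then convolved with the sampled temporal kernel
  res <- 6L; rn <- 20L * res
  rx <- ((1:rn) - 0.5) / res - 10
  ry <- 10 - ((1:rn) - 0.5) / res
  ds <- spikeflow:::.downsampleFrames(fr@frames, 20L, res)
  gp <- gridPositions(20L)
  X <- rep(rx, each = rn); Y <- rep(ry, times = rn)
  # column-major vectorization of an rn x rn matrix: rows (y) vary fastest
  S <- vapply(seq_len(dim(ds)[1]), function(f)
    sum(spatialDog(p, X - gp[ctr, "x"], Y - gp[ctr, "y"]) *
          as.vector(ds[f, , ])) / res^2, 0)
  nT <- ncol(cur)
  fIdx <- pmin(length(S), floor((seq_len(nT) - 1) / fr@frameInterval) + 1)
  h <- temporalKernel(p, seq(0, p@tSupport, by = 1))
  want <- numeric(nT)
  for (t in seq_len(nT)) {
    k <- 0:min(t - 1, length(h) - 1)
    want[t] <- 500 * sum(h[k + 1] * S[fIdx[t - k]])
  }
  expect_equal(cur[ctr, ], want, tolerance = 1e-8)
  # biphasic signature: positive onset transient, negative offset transient
  expect_gt(max(want[1:150]), 0)
  expect_lt(min(want[300:450]), 0)
})

test_that("the lattice response is translation-equivariant off the border", {
  sz <- 240L
  mk <- function(colPx) {
    fr <- array(0, dim = c(6, sz, sz))
    fr[, , colPx + 0:11] <- 1
    new("FrameSequence", frames = fr, frameInterval = 100 / 3,
        pxPerDegree = defaultPxPerDegree(), metadata = list())
  }
  p <- rgcParams(gain = 100)
  suppressWarnings({
    a <- filterFrames(mk(60), p, "ON")   # one lattice spacing = 12 px
    b <- filterFrames(mk(72), p, "ON")
  })
  # shifting the stimulus by one lattice column shifts the response rows
  colA <- 8; colB <- 9
  idxA <- (colA - 1) * 20 + 5:15
  idxB <- (colB - 1) * 20 + 5:15
  expect_equal(a[idxA, ], b[idxB, ], tolerance = 1e-9, ignore_attr = TRUE)
})
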