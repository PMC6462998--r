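# Random-dot kinematogram and drifting-bar stimulus generators.

test_that("dot field honours the 50/36/14 composition for any seed", {
  for (seed in c(1, 7, 123)) {
    f <- initDotField(-60, seed = seed)
    expect_equal(nrow(f@positions), 50L)
    expect_equal(sum(f@isRadial), 36L)
    expect_equal(sum(!f@isRadial), 14L)
    expect_true(all(f@ages >= 0 & f@ages < 100))
  }
})

test_that("expansion center placement and limits", {
  f <- initDotField(0, seed = 1)
  expect_equal(f@center, c(0, 0))
  f <- initDotField(-140, seed = 1)
  expect_equal(f@center, c(-140, 0))
  expect_error(initDotField(400, sizePx = 600), "off-screen")
})

test_that("radial dots point away from the center at every step", {
  f <- initDotField(-100, seed = 42)
  for (i in 1:18) {
    f <- stepDots(f, 100 / 3)$field
    rel <- sweep(f@positions[f@isRadial, ], 2, f@center)
    cosang <- rowSums(rel * f@directions[f@isRadial, ]) /
      sqrt(rowSums(rel^2))
    expect_true(all(cosang > 1 - 1e-9))
  }
})

test_that("a zero frame interval leaves the field unchanged", {
  f <- initDotField(20, seed = 3)
  g <- stepDots(f, 0)$field
  expect_identical(f@positions, g@positions)
  expect_identical(f@ages, g@ages)
})

test_that("expired dots are re-positioned with direction preserved", {
  f <- initDotField(20, seed = 3)
  old <- f
  f@ages[!f@isRadial][1] <- 99
  idx <- which(!f@isRadial)[1]
  set.seed(99)
  out <- stepDots(f, 2)
  expect_true(out$renewed[idx])
  expect_equal(out$field@directions[idx, ], old@directions[idx, ])
  expect_lt(out$field@ages[idx], 100)
})

test_that("with staggered ages about one third of dots renews per frame", {
  # Monte-Carlo oracle: expected renewal fraction = dt / lifetime = 1/3
  set.seed(7)
  fr <- replicate(40, {
    f <- initDotField(-60)
    mean(replicate(18, {
      out <- stepDots(f, 100 / 3)
      f <<- out$field
      mean(out$renewed)
    }))
  })
  expect_equal(mean(fr), 1 / 3, tolerance = 0.08)
})

test_that("mirrored displacement yields a statistically identical field", {
  set.seed(1)
  xs <- replicate(60, {
    f <- initDotField(-100)
    f@positions[, 1] - f@center[1]
  })
  set.seed(1)
  xm <- replicate(60, {
    f <- initDotField(100)
    -(f@positions[, 1] - f@center[1])
  })
  expect_gt(suppressWarnings(ks.test(as.vector(xs), as.vector(xm)))$p.value,
            0.01)
})

test_that("rendered dot stimulus has exact frame count and luminance bounds", {
  st <- makeDotStimulus(-60, duration = 200, sizePx = 200, seed = 5)
  expect_equal(nFrames(st), ceiling(200 / (100 / 3)))
  expect_true(all(st@frames >= 0 & st@frames <= 1))
  expect_identical(st@metadata$side, "left")
  # an empty trace renders to all-zero frames
  f0 <- initDotField(0, sizePx = 100, seed = 1)
  f0@positions <- f0@positions[0, , drop = FALSE]
  f0@directions <- f0@directions[0, , drop = FALSE]
  f0@ages <- numeric(0); f0@isRadial <- logical(0)
  fr <- renderDots(list(f0, f0), sizePx = 100)
  expect_true(all(fr@frames == 0))
})

test_that("a static single dot renders identical frames with one disc", {
  f <- initDotField(0, sizePx = 100, speed = 0, seed = 2)
  f@positions <- matrix(c(10, -20), 1); f@directions <- matrix(c(1, 0), 1)
  f@ages <- 0; f@isRadial <- FALSE
  st <- renderDots(list(f, f, f), sizePx = 100, dotRadiusPx = 4)
  expect_equal(st@frames[1, , ], st@frames[3, , ])
  expect_gt(max(st@frames[1, , ]), 0.9)
})

test_that("the seven displacement magnitudes map to 0.67-4.67 degrees", {
  lv <- displacementLevels()
  expect_equal(lv, seq(20L, 140L, 20L))
  deg <- lv / defaultPxPerDegree()
  expect_equal(deg[1], 0.67, tolerance = 1e-9)
  expect_equal(deg[7], 4.69, tolerance = 0.01)
})

test_that("bar stimulus with zero speed is static", {
  spec <- barStimulusSpec(list(barRegion(c(0, 1), orientation = 0,
                                         speed = 0)), duration = 100)
  st <- makeBarStimulus(spec, sizePx = 300)
  expect_equal(st@frames[1, , ], st@frames[nFrames(st), , ])
})

test_that("overlapping bar regions are rejected", {
  expect_error(barStimulusSpec(list(barRegion(c(0, 0.6), 0),
                                    barRegion(c(0.5, 1), pi / 4))),
               "overlap")
})

test_that("metadata mean orientation equals the area-weighted circular mean", {
  th1 <- 0.3; th2 <- 1.8
  spec <- barStimulusSpec(list(barRegion(c(0, 0.25), th1),
                               barRegion(c(0.25, 1), th2)), duration = 50)
  st <- makeBarStimulus(spec, sizePx = 240)
  # brute-force circular mean over region pixels
  a <- c(0.25, 0.75) * 240^2
  want <- (atan2(sum(a * sin(2 * c(th1, th2))),
                 sum(a * cos(2 * c(th1, th2)))) / 2) %% pi
  expect_equal(st@metadata$meanOrientationDeg, want * 180 / pi,
               tolerance = 1e-6)
})

test_that("the standard two-region test stimulus is valid model input", {
  st <- makeBarStimulus(defaultBarStimulusSpec(duration = 100))
  expect_s4_class(st, "FrameSequence")
  expect_true(all(st@frames >= 0 & st@frames <= 1))
  expect_equal(st@metadata$meanOrientationDeg, 50.87, tolerance = 0.01)
  expect_equal(st@metadata$meanDirectionDeg, 93.35, tolerance = 0.01)
})
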