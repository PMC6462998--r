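# Connectivity builders: weight equations, signs and symmetries.

mapV1 <- generateMap(seed = 11, period = pi, mirror = TRUE)
mapMT <- generateMap(seed = 12, period = 2 * pi, mirror = TRUE)

test_that("LGN afferents follow the Gabor sign mask and are excitatory", {
  cs <- buildLgnV1(mapV1, gain = 100, cutoff = 0.1)
  on <- synapses(cs$on); off <- synapses(cs$off)
  expect_true(all(on$weight >= 0))
  expect_true(all(off$weight >= 0))
  # sign-mask oracle on the lattice for a handful of cells
  pos <- gridPositions(20L)
  for (i in c(1L, 57L, 190L, 400L)) {
    rf <- gaborRF(center = pos[i, ], orientation = mapV1@theta[i],
                  phase = mapV1@phase[i], sigma_x = 2, sigma_y = 1)
    g <- gabor(rf, pos[, "x"], pos[, "y"])
    expect_setequal(on$pre[on$post == i], which(g > 0.1))
    expect_setequal(off$pre[off$post == i], which(-g > 0.1))
  }
  # every V1 excitatory cell has at least one afferent at the default cutoff
  both <- c(on$post, off$post)
  expect_true(all(1:400 %in% both))
})

test_that("a cutoff at the field maximum empties the connection set", {
  cs <- buildLgnV1(mapV1, gain = 100, cutoff = 1)
  expect_equal(nrow(synapses(cs$on)), 0L)
  expect_equal(nrow(synapses(cs$off)), 0L)
})

test_that("lateral excitation peaks for identical receptive fields", {
  cs <- buildV1Lateral(mapV1, g_e = 2, g_i = 5)
  s <- synapses(cs)
  exc <- s[s$pre <= 400 & s$weight > 0, ]
  # two excitatory cells with nearly identical fields: neighbors on the map
  # cannot beat the theoretical maximum g_e * 1
  expect_lte(max(exc$weight), 2 + 1e-9)
  expect_false(any(s$pre == s$post))
})

test_that("inhibition is strongest at a phase difference of pi", {
  pos <- .row <- NULL
  cs <- buildV1Lateral(mapV1, g_e = 1, g_i = 3, sigma_lat = 1e6)
  s <- synapses(cs)
  inh <- s[s$pre > 400 & s$post <= 400, ]
  prefs <- spikeflow:::.corticalPrefs(mapV1)
  dph <- abs(((prefs$phase[inh$pre] - prefs$phase[inh$post] - pi) %% (2 * pi)))
  dph <- pmin(dph, 2 * pi - dph)   # distance from the anti-phase point
  oriS <- pmax(cos(2 * (prefs$theta[inh$pre] - prefs$theta[inh$post])), 0)
  # at matched orientation, weights decay with distance from anti-phase
  sel <- oriS > 0.95
  expect_lt(cor(dph[sel], abs(inh$weight[sel]) / oriS[sel]), -0.5)
  expect_true(all(inh$weight <= 0))
})

test_that("V1->MT weights obey the gated cosine formula exhaustively", {
  k_c <- 7
  cs <- buildV1Mt(mapV1, mapMT, k_c = k_c, prune = 0)
  s <- synapses(cs)
  prefsV1 <- spikeflow:::.corticalPrefs(mapV1)
  prefsMT <- spikeflow:::.corticalPrefs(mapMT)
  dog <- rgcParams(a_c = 1, a_s = 0.9, sigma_c = 0.8, sigma_s = 2.4)
  W <- matrix(0, 400, 500)
  W[cbind(s$pre, s$post)] <- s$weight
  for (j in seq(1, 500, by = 17)) {
    for (i in seq(1, 400, by = 13)) {
      phi <- angularDifference(prefsMT$theta[j], prefsV1$theta[i])
      want <- if (phi <= pi / 2)
        k_c * spatialDog(dog, prefsMT$pos[j, 1] - prefsV1$pos[i, 1],
                         prefsMT$pos[j, 2] - prefsV1$pos[i, 2]) * cos(phi)
      else 0
      expect_equal(W[i, j], unname(want), tolerance = 1e-12)
    }
  }
  # phi = pi/3 pair weight ratio to a phi = 0 pair at equal offset
  expect_equal(k_c * spatialDog(dog, 1, 1) * cos(pi / 3),
               k_c * spatialDog(dog, 1, 1) * 0.5)
  expect_error(buildV1Mt(mapV1, mapMT, k_c = -1), "k_c")
})

test_that("MST template weights match the printed formula", {
  spec <- mstTemplateSpec("expansion", focalX = -5, d = 0.15, tol = pi / 8,
                          sigma_I = 2)
  mtPos <- gridPositions(20L)
  mtDir <- as.vector(mapMT@theta)
  mstPos <- c(3, -1)
  w <- mstTemplateWeight(spec, mtPos, mtDir, mstPos)
  for (i in seq(1, 400, by = 7)) {
    fx <- -5 - mtPos[i, 1]; fy <- 0 - mtPos[i, 2]
    delta <- atan2(fy, fx)
    elig <- angularDifference(mtDir[i], delta + pi) <= pi / 8 &&
      (fx^2 + fy^2) > 1e-12
    want <- as.numeric(elig) * exp(-0.15 * (fx^2 + fy^2)) *
      exp(-((mtPos[i, 1] - 3)^2 + (mtPos[i, 2] + 1)^2) / (2 * 4)) /
      (2 * pi * 4)
    expect_equal(unname(w[i]), unname(want), tolerance = 1e-12)
  }
})

test_that("MT cells orthogonal to the radial line or at the focus get zero", {
  spec <- mstTemplateSpec("expansion", focalX = 0, d = 0.1, tol = pi / 8,
                          sigma_I = 2)
  # cell at (4.5, 0): away direction is 0; orthogonal preference pi/2
  w <- mstTemplateWeight(spec, matrix(c(4.5, 0), 1), pi / 2, c(0.5, 0.5))
  expect_equal(w, 0)
  # cell exactly at the focal point: undefined radial angle -> weight 0
  w0 <- mstTemplateWeight(spec, matrix(c(0, 0), 1), 1.2, c(0.5, 0.5))
  expect_equal(w0, 0)
  # eligible cells scale as exp(-d r^2)
  w1 <- mstTemplateWeight(spec, matrix(c(2, 0), 1), 0, c(0, 0))
  w2 <- mstTemplateWeight(spec, matrix(c(4, 0), 1), 0, c(0, 0))
  sigmaPart <- exp(-c(4, 16) / (2 * 4)) / (2 * pi * 4)
  expect_equal(w2 / w1, exp(-0.1 * (16 - 4)) * sigmaPart[2] / sigmaPart[1],
               tolerance = 1e-12)
})

test_that("template weights are mirror symmetric", {
  mtPos <- gridPositions(20L)
  set.seed(3)
  dirs <- runif(400, 0, 2 * pi)
  a <- mstTemplateWeight(mstTemplateSpec("expansion", focalX = -5),
                         mtPos, dirs, c(2, 1))
  # reflect focal, positions and directions about the vertical axis
  b <- mstTemplateWeight(mstTemplateSpec("expansion", focalX = 5),
                         cbind(-mtPos[, 1], mtPos[, 2]),
                         (pi - dirs) %% (2 * pi), c(-2, 1))
  expect_equal(unname(a), unname(b), tolerance = 1e-9)
})

test_that("MST lateral weights follow the focal-similarity sign rule", {
  css <- buildMstLateral(gain = 2, sigma_ts = 3, prune = 0)
  focal <- mstFocalAssignment()
  pos <- gridPositions(20L)
  s <- synapses(css$ee)
  same <- focal[s$pre] == focal[s$post]
  d2 <- (pos[s$pre, 1] - pos[s$post, 1])^2 +
        (pos[s$pre, 2] - pos[s$post, 2])^2
  want <- ifelse(same, 1, -1) * 2 * exp(-d2 / 18)
  expect_equal(s$weight, want, tolerance = 1e-12)
  # adjacent same-focal pair approaches +gain, different-focal pair -gain
  expect_gt(max(s$weight[same]), 2 * exp(-1 / 18) - 1e-9)
  expect_lt(min(s$weight[!same]), 0)
  # inter-layer connections are all inhibitory
  expect_true(all(synapses(css$ec)$weight <= 0))
  expect_true(all(synapses(css$ce)$weight <= 0))
  ec <- synapses(css$ec)
  dfo <- (focal[ec$pre] - focal[ec$post])^2
  d2e <- (pos[ec$pre, 1] - pos[ec$post, 1])^2 +
         (pos[ec$pre, 2] - pos[ec$post, 2])^2
  expect_equal(ec$weight, -2 * exp(-d2e / 18) * exp(-dfo / 18),
               tolerance = 1e-12)
})

test_that("LIP afferents follow the decision rule and mirror exactly", {
  lip <- buildMstLip(g_e = 3, g_i = 0.5, g_lip = 9)
  focal <- mstFocalAssignment()
  e <- synapses(lip$e)
  wL <- e$weight[e$post == 1][order(e$pre[e$post == 1])]
  wR <- e$weight[e$post == 2][order(e$pre[e$post == 2])]
  expect_true(all(wL[focal == -5] == 3))
  expect_true(all(wL[focal != -5] == -0.5))
  expect_true(all(wR[focal == 5] == 3))
  # center-focal expansion cells inhibit both sides
  expect_true(all(wL[focal == 0] == -0.5 & wR[focal == 0] == -0.5))
  # contraction cells inhibit both sides
  expect_true(all(synapses(lip$c)$weight == -0.5))
  # mirror: reflecting the MST grid about x maps left weights onto right
  pos <- gridPositions(20L)
  refl <- match(paste(-pos[, 1], pos[, 2]), paste(pos[, 1], pos[, 2]))
  expect_equal(unname(wL[refl]), unname(wR))
  # mutual inhibition
  expect_equal(synapses(lip$lip)$weight, c(-9, -9))
})

test_that("feedback loops are retinotopic and vanish at zero gain", {
  fb <- buildFeedbackInhibition(g_fb_e = 10, g_fb_i = 2, sigma_fb = 2)
  s <- synapses(fb$v1_trn_on)
  # modal target of cell i is i (retinotopic alignment census)
  strongest <- vapply(split(s, s$pre), function(d)
    d$post[which.max(d$weight)], 0L)
  expect_equal(unname(strongest), as.integer(names(strongest)))
  expect_true(all(synapses(fb$trn_lgn_on)$weight < 0))
  expect_equal(synapses(fb$in_lgn_off)$pre, synapses(fb$in_lgn_off)$post)
  fb0 <- buildFeedbackInhibition(g_fb_e = 0, g_fb_i = 0)
  expect_equal(sum(vapply(fb0, function(x) nrow(synapses(x)), 0L)), 0L)
})

test_that("builders are deterministic given maps and parameters", {
  a <- buildV1Mt(mapV1, mapMT, k_c = 2)
  b <- buildV1Mt(mapV1, mapMT, k_c = 2)
  expect_identical(synapses(a), synapses(b))
})
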