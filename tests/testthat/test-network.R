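# Network assembly and full simulation behaviour.

test_that("the assembled network reproduces the published layer sizes", {
  cen <- networkCensus(defaultNetwork())
  ly <- cen$layers
  expect_equal(ly$n[ly$label == "V1"], 500L)     # 400 exc + 100 inh
  expect_equal(ly$n[ly$label == "MT"], 500L)
  for (lbl in c("LGN_ON", "LGN_OFF", "IN_ON", "IN_OFF", "TRN_ON", "TRN_OFF",
                "MSTe", "MSTc"))
    expect_equal(ly$n[ly$label == lbl], 400L)
  expect_equal(ly$n[ly$label == "LIP"], 2L)
  expect_true(all(cen$projections$n_syn > 0))
})

test_that("size-invariant violations name the offending field", {
  expect_error(assembleNetwork(networkConfig(list(layerSizes = list(grid = 10L)))),
               "layerSizes\\$grid")
  expect_error(assembleNetwork(networkConfig(list(layerSizes = list(lip = 3L)))),
               "layerSizes\\$lip")
})

test_that("zero feedback gain yields zero feedback synapses", {
  cfg <- networkConfig(list(gains = list(fb_e = 0, fb_i = 0)))
  cen <- networkCensus(assembleNetwork(cfg))
  pr <- cen$projections
  expect_equal(pr$n_syn[pr$name == "trn_lgn_on"], 0L)
  expect_equal(pr$n_syn[pr$name == "v1_in_off"], 0L)
})

test_that("synapse counts depend on the config, not on run seeds", {
  a <- networkCensus(defaultNetwork())$projections$n_syn
  b <- networkCensus(assembleNetwork())$projections$n_syn
  expect_identical(a, b)
})

test_that("identical seeds reproduce the simulation bit for bit", {
  net <- defaultNetwork()
  st <- makeDotStimulus(-100, duration = 150, seed = 3)
  suppressWarnings({    # short stimulus: zero-padded history is expected
    a <- runNetwork(net, st, noiseSeed = 11)
    b <- runNetwork(net, st, noiseSeed = 11)
  })
  for (lbl in names(a@spikes))
    expect_identical(spikeEvents(a, lbl), spikeEvents(b, lbl))
})

test_that("running longer than the stimulus is rejected", {
  net <- defaultNetwork()
  st <- makeDotStimulus(-100, duration = 100, seed = 3)
  expect_error(runNetwork(net, st, duration = 300), "exceeds")
})

test_that("a blank stimulus leaves the two LIP channels balanced", {
  net <- defaultNetwork()
  blank <- new("FrameSequence", frames = array(0, c(9, 600, 600)),
               frameInterval = 100 / 3, pxPerDegree = defaultPxPerDegree(),
               metadata = list())
  suppressWarnings(res <- runNetwork(net, blank, noiseSeed = 5))
  ev <- spikeEvents(res, "LIP")
  nL <- sum(ev$neuron == 1); nR <- sum(ev$neuron == 2)
  expect_lt(abs(nL - nR), 0.5 * max(nL + nR, 10))
  # sensory layers are essentially silent without contrast
  expect_lt(nrow(spikeEvents(res, "MSTe")), 20)
})

test_that("a mirrored stimulus swaps the left/right evidence", {
  net <- defaultNetwork()
  st <- makeDotStimulus(-140, duration = 600, seed = 5)
  stM <- st
  stM@frames <- st@frames[, , dim(st@frames)[3]:1, drop = FALSE]
  focal <- mstFocalAssignment()
  g <- function(res) {
    cnt <- tabulate(spikeEvents(res, "MSTe")$neuron, 400)
    c(L = sum(cnt[focal == -5]), R = sum(cnt[focal == 5]))
  }
  a <- g(runNetwork(net, st, noiseSeed = 9))
  b <- g(runNetwork(net, stM, noiseSeed = 9))
  expect_gt(a["L"], a["R"])   # left-displaced flow favors the left group
  expect_gt(b["R"], b["L"])   # its mirror favors the right group
})

test_that("rasters export to delimited text and read back", {
  net <- defaultNetwork()
  st <- makeDotStimulus(60, duration = 100, seed = 2)
  suppressWarnings(res <- runNetwork(net, st, noiseSeed = 4))
  dir <- file.path(tempdir(), "rasters")
  paths <- exportRasters(res, dir)
  expect_true(all(file.exists(paths)))
  v1 <- readSpikes(file.path(dir, "V1.tsv"), layer = "V1", n = 500,
                   duration = 100)
  expect_equal(spikeEvents(v1), spikeEvents(res, "V1"))
})
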