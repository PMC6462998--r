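# Population-vector decoding and the left/right decision analysis.

test_that("decoding spikes from one preference returns that angle", {
  sd <- spikeDataOf(rep(3L, 12), seq(1, 12), n = 5, duration = 20)
  prefs <- c(0.1, 0.4, 30 * pi / 180, 1.2, 2)
  d <- populationDecode(sd, prefs, period = pi)
  expect_equal(decodedAngle(d), 30)
  d2 <- populationDecode(sd, prefs, period = 2 * pi)
  expect_equal(decodedAngle(d2), 30)
})

test_that("equal counts at 0 and 90 degrees decode to 45 in direction mode", {
  sd <- spikeDataOf(c(1L, 1L, 2L, 2L), c(1, 2, 3, 4), n = 2, duration = 10)
  d <- populationDecode(sd, c(0, pi / 2), period = 2 * pi)
  expect_equal(decodedAngle(d), 45)
})

test_that("counts 10/20/10 at 0/90/180 degrees decode to 90", {
  sd <- spikeDataOf(rep(c(1L, 2L, 3L), c(10, 20, 10)), seq_len(40),
                    n = 3, duration = 50)
  d <- populationDecode(sd, c(0, pi / 2, pi), period = 2 * pi)
  expect_equal(decodedAngle(d), 90)
})

test_that("decoder equals the brute-force vector sum on random cases", {
  set.seed(5)
  for (period in c(pi, 2 * pi)) {
    for (rep_ in 1:50) {
      n <- sample(3:30, 1)
      prefs <- runif(n, 0, period)
      counts <- rpois(n, 3)
      if (sum(counts) == 0) counts[1] <- 1
      ev <- data.frame(neuron = rep(seq_len(n), counts),
                       time = seq_len(sum(counts)))
      sd <- spikeDataOf(ev$neuron, ev$time, n = n,
                        duration = sum(counts) + 1)
      d <- populationDecode(sd, prefs, period = period)
      th <- if (isTRUE(all.equal(period, pi))) 2 * prefs else prefs
      S <- sum(counts * sin(th)); C <- sum(counts * cos(th))
      if (abs(S) < 1e-12 && abs(C) < 1e-12) {
        expect_false(d@defined)
      } else {
        want <- atan2(S, C)
        want <- if (isTRUE(all.equal(period, pi))) (want / 2) %% pi
                else want %% (2 * pi)
        expect_equal(decodedAngle(d), want * 180 / pi, tolerance = 1e-9)
      }
    }
  }
})

test_that("decoder is equivariant under rotation of all preferences", {
  set.seed(8)
  prefs <- runif(10, 0, 2 * pi)
  counts <- rpois(10, 4) + 1
  sd <- spikeDataOf(rep(1:10, counts), seq_len(sum(counts)), n = 10,
                    duration = sum(counts) + 1)
  base <- decodedAngle(populationDecode(sd, prefs, period = 2 * pi))
  for (alpha in c(0.3, 1.5, 4)) {
    rot <- decodedAngle(populationDecode(sd, (prefs + alpha) %% (2 * pi),
                                         period = 2 * pi))
    expect_equal((rot - base) %% 360, (alpha * 180 / pi) %% 360,
                 tolerance = 1e-6)
  }
})

test_that("zero spikes yield an undefined decode, not a number", {
  sd <- spikeDataOf(integer(0), numeric(0), n = 4, duration = 10)
  d <- populationDecode(sd, c(0, 1, 2, 3), period = 2 * pi)
  expect_false(d@defined)
  expect_true(is.na(decodedAngle(d)))
})

test_that("lipRates computes windowed rates in Hz", {
  sd <- spikeDataOf(c(1L, 1L, 2L), c(10, 30, 45), n = 2, duration = 100)
  tr <- lipRates(sd, window = 50, step = 25)
  expect_equal(tr@times, c(0, 25, 50))
  expect_equal(tr@left, c(2, 1, 0) / 0.05)
  expect_equal(tr@right, c(1, 1, 0) / 0.05)
})

test_that("a uniformly higher side wins with zero latency", {
  tr <- list(times = seq(0, 550, 10), left = rep(5, 56),
             right = rep(5.5, 56))
  d <- decideFromRates(tr)
  expect_equal(decision(d), "right")
  expect_equal(decisionLatency(d), 0)
})

test_that("a single swap at 350 ms gives latency 350", {
  times <- seq(0, 550, 10)
  left <- ifelse(times < 350, 10, 2)
  right <- ifelse(times < 350, 2, 10)
  d <- decideFromRates(list(times = times, left = left, right = right))
  expect_equal(decision(d), "right")
  # brute-force scan of the prevail condition
  win <- right; lose <- left
  first <- max(which(win < lose)) + 1
  expect_equal(decisionLatency(d), times[first])
  expect_equal(decisionLatency(d), 350)
})

test_that("silence or exact ties are undecided", {
  z <- rep(0, 20)
  d <- decideFromRates(list(times = seq(0, 190, 10), left = z, right = z))
  expect_equal(decision(d), "undecided")
  expect_true(is.na(decisionLatency(d)))
})

test_that("the decision is invariant to joint rescaling of both series", {
  set.seed(2)
  times <- seq(0, 550, 10)
  left <- rpois(56, 3); right <- rpois(56, 3) + c(rep(0, 30), rep(2, 26))
  a <- decideFromRates(list(times = times, left = left, right = right))
  b <- decideFromRates(list(times = times, left = 7.3 * left,
                            right = 7.3 * right))
  expect_equal(decision(a), decision(b))
  expect_equal(decisionLatency(a), decisionLatency(b))
})

test_that("experiment summaries aggregate accuracy, latency and the trend", {
  res <- data.frame(
    displacement = rep(c(20, 60, 140), each = 4),
    side = rep(c("left", "right"), 6),
    trial = rep(1:2, each = 2),
    decision = c("left", "right", "left", "left",
                 "left", "right", "left", "right",
                 "left", "right", "left", "right"),
    correct = c(TRUE, TRUE, TRUE, FALSE,
                TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE, TRUE, TRUE),
    latency = c(500, 520, 480, NA, 350, 360, 340, 330, 150, 160, 140, 170),
    nLeft = 10, nRight = 10)
  s <- summarizeExperiment(res)
  expect_equal(nrow(s$byCondition), 6L)
  expect_equal(s$accuracy, mean(res$correct))
  expect_lt(s$spearmanRho, 0)
  expect_equal(s$byMagnitude$meanLatency[3], 155)
})
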