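test_that("empty configuration yields an all-zero recording", {
  g <- testGrid(4, 4)
  sim <- simulateRecording(simConfig(g, 2000, 0.5, noiseSigmaUv = 0), 1)
  expect_true(all(voltageMatrix(sim$recording) == 0))
  expect_identical(nrow(sim$truth@spikes), 0L)
})

test_that("generation is a pure function of (config, seed)", {
  g <- testGrid(6, 6)
  cfg <- simConfig(g, 2000, 2,
                   neurons = list(neuronSpec(21.04, 21.04, baselineRateHz = 8)),
                   noiseSigmaUv = 3, driftSlopeUvPerS = 0.5)
  a <- simulateRecording(cfg, 99)
  b <- simulateRecording(cfg, 99)
  expect_identical(voltageMatrix(a$recording), voltageMatrix(b$recording))
  expect_identical(a$truth@spikes, b$truth@spikes)
  c <- simulateRecording(cfg, 100)
  expect_false(identical(voltageMatrix(a$recording),
                         voltageMatrix(c$recording)))
})

test_that("planted spike peaks match the template amplitude analytically", {
  g <- testGrid(8, 8)
  # neuron exactly on electrode (3,3) center
  e <- electrodeIndex(g, 3, 3)
  pos <- electrodePositions(g, e)
  cfg <- simConfig(g, 2000, 5,
                   neurons = list(neuronSpec(pos[1], pos[2],
                                             baselineRateHz = 5)),
                   noiseSigmaUv = 0)
  sim <- simulateRecording(cfg, 4)
  tt <- truthTrains(sim$truth)[[1]]
  expect_gt(length(tt), 0)
  V <- voltageMatrix(sim$recording)
  # negative peak of -peakAmpUv at the soma electrode at each spike sample
  samp <- round(tt[1] * 2000) + 1L
  expect_equal(V[e, samp], -18, tolerance = 1e-12)
  expect_equal(max(abs(V)), 18, tolerance = 1e-12)
  # neighbor at one pitch carries the Gaussian-decayed amplitude
  e2 <- electrodeIndex(g, 3, 4)
  expect_equal(V[e2, samp], -18 * exp(-10.52^2 / (2 * 15^2)),
               tolerance = 1e-9)
})

test_that("spike counts follow the planted Poisson rate", {
  g <- testGrid(4, 4)
  cfg <- simConfig(g, 2000, 10,
                   neurons = list(neuronSpec(10.52, 10.52,
                                             baselineRateHz = 5)),
                   noiseSigmaUv = 0)
  n <- length(truthTrains(simulateRecording(cfg, 8)$truth)[[1]])
  # Poisson(50): 99.9% interval
  expect_gt(n, 27)
  expect_lt(n, 76)
})

test_that("voltage superposes across neurons with one shared noise field", {
  g <- testGrid(8, 8)
  nA <- neuronSpec(10.52, 10.52, baselineRateHz = 10, seed = 101)
  nB <- neuronSpec(63.12, 63.12, baselineRateHz = 10, seed = 202)
  vOf <- function(neurons)
    voltageMatrix(simulateRecording(
      simConfig(g, 2000, 2, neurons = neurons, noiseSigmaUv = 0), 5)$recording)
  expect_identical(vOf(list(nA, nB)), vOf(list(nA)) + vOf(list(nB)))
})

test_that("plane-wave peak times are affine in projected position", {
  g <- ElectrodeGrid(12, 12, 10.52)
  w <- waveSpec(onsetS = 0.1, mode = "plane", direction = c(1, 0),
                speedUmPerS = 500, carrierFreqHz = 10, ampUv = 50,
                durationS = 0.15)
  cfg <- simConfig(g, 2000, 0.8, waves = list(w), noiseSigmaUv = 0)
  rec <- simulateRecording(cfg, 1)$recording
  ev <- list(onset_s = 0, offset_s = 0.79)
  pk <- peakTimeMap(rec, ev, seq_len(nElectrodes(g)))
  proj <- electrodePositions(g)[, "x_um"]
  fit <- stats::lm(pk ~ proj)
  expect_equal(unname(stats::coef(fit)[2]), 1 / 500, tolerance = 0.02)
  expect_gte(summary(fit)$r.squared, 0.999)
  # planted peak-time helper agrees with the measured map
  expected <- waveOnsetTimes(w, g) + wavePeakOffset(w, 2000)
  expect_lt(max(abs(pk - expected)), 1e-3)
})

test_that("configuration contract violations raise errors", {
  g <- testGrid(4, 4)
  expect_error(simConfig(g, -1, 10), "fs")
  expect_error(simConfig(g, 2000, 0), "durationS")
  expect_error(simConfig(g, 2000, 1,
                         neurons = list(neuronSpec(1e5, 0))),
               "bounding box")
  expect_error(neuronSpec(0, 0, peakAmpUv = -1), "peakAmpUv")
  expect_error(waveSpec(0, speedUmPerS = 0), "speedUmPerS")
  expect_error(couplingSpec(1, 2, 1.5, 10), "couplingProb")
})

test_that("assembloid coupling plants triggered spikes as specified", {
  g <- testGrid(10, 4)
  mk <- function(prob, jitter = 0, rate = 3) {
    cfg <- simConfig(g, 2000, 30,
                     neurons = list(neuronSpec(10.52, 10.52,
                                               baselineRateHz = rate),
                                    neuronSpec(10.52, 84.16,
                                               baselineRateHz = 0)),
                     couplings = list(couplingSpec(1, 2, prob, 20, jitter)),
                     noiseSigmaUv = 0, regionSplitRow = 5L)
    simulateAssembloidRecording(cfg, 7)
  }
  # coupling 0: no triggered spikes
  expect_identical(nrow(mk(0)$truth@parentage), 0L)
  # coupling 1, no jitter: post train = pre train + 20 ms exactly
  sim <- mk(1)
  tr <- truthTrains(sim$truth)
  expect_equal(tr[[2]], tr[[1]] + 0.020, tolerance = 1e-12)
  expect_true(all(sim$truth@spikes$triggered[sim$truth@spikes$neuron == 2]))
  # region labels follow the split
  lab <- regionLabels(sim$recording)
  rows <- electrodeRowCol(g, seq_len(nElectrodes(g)))[, "row"]
  expect_identical(lab, ifelse(rows <= 5, "striatum", "midbrain"))
  # coupling 0.5: triggered count inside the binomial 99% interval
  sim2 <- mk(0.5, jitter = 2, rate = 7)   # ~200 pre spikes over 30 s
  npre <- length(truthTrains(sim2$truth)[[1]])
  ntrig <- nrow(sim2$truth@parentage)
  expect_gt(ntrig, qbinom(0.005, npre, 0.5))
  expect_lt(ntrig, qbinom(0.995, npre, 0.5))
  # invalid split row
  cfgBad <- simConfig(g, 2000, 1, regionSplitRow = 10L)
  expect_error(simulateAssembloidRecording(cfgBad, 1), "regionSplitRow")
})
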