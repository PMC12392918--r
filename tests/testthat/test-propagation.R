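test_that("oscillation event detection separates waves from noise", {
  g <- testGrid(12, 12)
  # noise only: no events
  simN <- simulateRecording(simConfig(g, 2000, 3, noiseSigmaUv = 3), 61)
  expect_identical(nrow(detectOscillationEvents(simN$recording)), 0L)
  # one planted 1 s wave: exactly one event, Jaccard >= 0.7
  w <- waveSpec(onsetS = 1, mode = "plane", direction = c(1, 0),
                speedUmPerS = 1e6, carrierFreqHz = 6, ampUv = 50,
                durationS = 1)
  simW <- simulateRecording(simConfig(g, 2000, 3, waves = list(w),
                                      noiseSigmaUv = 3), 62)
  ev <- detectOscillationEvents(simW$recording)
  expect_identical(nrow(ev), 1L)
  expect_gte(intervalJaccard(ev$onset_s, ev$offset_s, 1, 2), 0.7)
  # degenerate recording
  rec1 <- MEARecording(matrix(0, nElectrodes(g), 1), 2000, g)
  expect_error(detectOscillationEvents(rec1), "too short")
})

test_that("propagating electrodes recover the planted extent mask", {
  g <- testGrid(12, 12)
  rows <- electrodeRowCol(g, seq_len(nElectrodes(g)))[, "row"]
  mask <- which(rows <= 6)
  mkRec <- function(amp, noise) {
    w <- waveSpec(onsetS = 0.2, mode = "plane", direction = c(1, 0),
                  speedUmPerS = 2000, carrierFreqHz = 10, ampUv = amp,
                  durationS = 0.15, extentMask = mask)
    simulateRecording(simConfig(g, 2000, 1.2, waves = list(w),
                                noiseSigmaUv = noise), 63)$recording
  }
  evw <- list(onset_s = 0.15, offset_s = 1.1)
  # noise-free: exact recovery
  expect_identical(propagatingElectrodes(mkRec(50, 0), evw), mask)
  # sub-threshold amplitude: empty set
  expect_identical(propagatingElectrodes(mkRec(20, 0), evw), integer())
  # with 3 uV noise: Jaccard >= 0.95
  expect_gte(jaccardIndex(propagatingElectrodes(mkRec(50, 3), evw), mask),
             0.95)
})

test_that("peak time maps respect simultaneity and tie-breaking", {
  g <- testGrid(6, 6)
  w <- waveSpec(onsetS = 0.2, mode = "plane", direction = c(1, 0),
                speedUmPerS = 1e9, carrierFreqHz = 10, ampUv = 50,
                durationS = 0.2)
  rec <- simulateRecording(simConfig(g, 2000, 1, waves = list(w),
                                     noiseSigmaUv = 0), 64)$recording
  ev <- list(onset_s = 0.1, offset_s = 0.9)
  pk <- peakTimeMap(rec, ev, seq_len(36))
  expect_lte(diff(range(pk)), 1 / 2000)
  # single electrode map
  expect_length(peakTimeMap(rec, ev, 7L), 1L)
  # ties broken by the earliest sample
  recT <- MEARecording(matrix(rep(c(0, 5, 1, 5, 0), each = 1), 1, 5),
                       1000, ElectrodeGrid(1, 1))
  evT <- list(onset_s = 0, offset_s = 0.004)
  expect_equal(unname(peakTimeMap(recT, evT, 1L)), 0.001)
})

test_that("recruitment series conserve electrode counts", {
  pk <- c(0.01, 0.011, 0.012, 0.05)
  rs <- recruitmentSeries(pk, binS = 0.005)
  expect_identical(sum(rs$counts), 4L)
  # all peaks in one bin
  rs1 <- recruitmentSeries(rep(0.003, 10), binS = 0.005)
  expect_identical(rs1$counts[1], 10L)
  expect_identical(sum(rs1$counts > 0), 1L)
  # empty set: all-zero series over the requested span
  rs0 <- recruitmentSeries(numeric(), binS = 0.005, durationS = 0.05)
  expect_identical(sum(rs0$counts), 0L)
  expect_length(rs0$counts, 10L)
  expect_error(recruitmentSeries(pk, binS = 0), "binS")
})

test_that("velocity reflects the slope of cumulative recruitment", {
  # uniform recruitment: max and mean slope agree with the true rate
  rs <- list(counts = rep(5L, 40), binS = 0.005)
  pv <- propagationVelocity(rs)
  expect_false(pv$degenerate)
  expect_equal(pv$velocity, 1000)
  expect_equal(pv$meanVelocity, 1000)
  # simultaneous recruitment degenerates to total / binS
  rs1 <- list(counts = c(0L, 144L, 0L), binS = 0.005)
  pv1 <- propagationVelocity(rs1)
  expect_true(pv1$degenerate)
  expect_equal(pv1$velocity, 144 / 0.005)
  expect_error(propagationVelocity(list(counts = integer(), binS = 0.005)),
               "empty")
})

test_that("propagation area converts electrode counts exactly", {
  g <- ElectrodeGrid()                      # full default array
  pa <- propagationArea(seq_len(nElectrodes(g)), g)
  expect_identical(pa$nElectrodes, 236880L)
  expect_equal(pa$areaMm2, 236880 * 110.67 / 1e6)
  expect_equal(pa$areaMm2, 26.21, tolerance = 0.001)
  # empty set
  p0 <- propagationArea(integer(), g)
  expect_identical(p0$nElectrodes, 0L)
  expect_identical(p0$areaMm2, 0)
  # half mask halves the count exactly
  gs <- testGrid(10, 10)
  full <- seq_len(100); half <- seq_len(50)
  expect_equal(propagationArea(half, gs)$nElectrodes,
               propagationArea(full, gs)$nElectrodes / 2)
})

test_that("endpoint aggregation averages within organoid and condition", {
  df <- data.frame(organoid_id = c("o1", "o1", "o1", "o2"),
                   condition = c("before", "before", "before", "before"),
                   velocity = c(100, 120, 140, 80))
  agg <- aggregateEndpoint(df, "velocity")
  expect_equal(agg$mean_value[agg$organoid == "o1"], 120)
  expect_equal(agg$mean_value[agg$organoid == "o2"], 80)
  # matches a brute-force group-by recount on random data
  set.seed(71)
  df2 <- data.frame(organoid_id = sample(c("a", "b", "c"), 60, TRUE),
                    condition = sample(c("x", "y"), 60, TRUE),
                    velocity = rnorm(60))
  agg2 <- aggregateEndpoint(df2, "velocity")
  for (r in seq_len(nrow(agg2))) {
    sel <- df2$organoid_id == agg2$organoid[r] &
      df2$condition == agg2$condition[r]
    expect_equal(agg2$mean_value[r], mean(df2$velocity[sel]))
  }
  # empty group absent, not zero
  expect_false(any(agg2$n_events == 0))
})
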