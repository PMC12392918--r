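test_that("adjacent electrodes with coincident trains merge into one soma", {
  g <- testGrid(8, 8)
  train <- seq(0.5, 10, by = 0.5)[1:20]
  ev <- rep(list(numeric()), nElectrodes(g))
  e1 <- electrodeIndex(g, 4, 4); e2 <- electrodeIndex(g, 4, 5)
  ev[[e1]] <- train
  ev[[e2]] <- train + 0.002          # 2 ms < 10 ms ISI window
  ss <- identifySomas(ev, g)
  expect_identical(length(ss), 1L)
  expect_identical(somaMembers(ss)[[1]], sort(c(e1, e2)))
  # dedup at 1 ms: events 2 ms apart stay, so the union keeps 40? no:
  # the pairs are 2 ms apart -> both kept; n_spikes = 40
  expect_identical(somaTable(ss)$n_spikes, 40L)
  # with sub-ms offsets the union collapses to 20 spikes
  ev[[e2]] <- train + 0.0005
  ss2 <- identifySomas(ev, g)
  expect_identical(somaTable(ss2)$n_spikes, 20L)
  expect_equal(somaTrains(ss2)[[1]], train)  # earliest time kept
})

test_that("qualifying pairs beyond 50 um stay separate somas", {
  g <- testGrid(8, 8)
  train <- seq(0.5, 10, by = 0.5)[1:20]
  ev <- rep(list(numeric()), nElectrodes(g))
  # 6 columns apart = 63.1 um >= 50 um: no merge edge possible
  e1 <- electrodeIndex(g, 4, 1); e2 <- electrodeIndex(g, 4, 7)
  ev[[e1]] <- train; ev[[e2]] <- train
  ss <- identifySomas(ev, g)
  expect_identical(length(ss), 2L)
  expect_true(all(somaTable(ss)$n_electrodes == 1L))
  expect_gt(electrodeDistanceUm(g, e1, e2), 50)
})

test_that("the same-count criterion floors are enforced", {
  g <- testGrid(8, 8)
  ev <- rep(list(numeric()), nElectrodes(g))
  e1 <- electrodeIndex(g, 4, 4); e2 <- electrodeIndex(g, 4, 5)
  # only 3 coincidences < 10 ms: fails min_same = 5 -> no merge
  ev[[e1]] <- c(1, 2, 3, 10, 20, 30)
  ev[[e2]] <- c(1.002, 2.002, 3.002, 15, 25, 35)
  ss <- identifySomas(ev, g)
  expect_true(all(somaTable(ss)$n_electrodes == 1L))
  # clearly outside the 10 ms window: no merge
  ev[[e1]] <- seq(1, 10, by = 1)
  ev[[e2]] <- seq(1, 10, by = 1) + 0.011
  expect_true(all(somaTable(identifySomas(ev, g))$n_electrodes == 1L))
  # just inside the window: merges
  ev[[e2]] <- seq(1, 10, by = 1) + 0.009
  expect_identical(length(identifySomas(ev, g)), 1L)
  # the same-count window is strict: |dt| = 16 ms fails a 16 ms window
  # (binary-exact value), |dt| just below it succeeds
  ev[[e2]] <- seq(1, 10, by = 1) + 0.015625
  expect_true(all(somaTable(identifySomas(ev, g, isiMs = 15.625))$n_electrodes
                  == 1L))
  expect_identical(length(identifySomas(ev, g, isiMs = 15.626)), 1L)
})

test_that("matched coincidence counting is symmetric and order-free", {
  set.seed(33)
  for (r in 1:25) {
    a <- randTrain(sample(0:25, 1), span = 5)
    b <- randTrain(sample(0:25, 1), span = 5)
    expect_identical(matchedCoincidences(a, b, 0.01, FALSE),
                     matchedCoincidences(b, a, 0.01, FALSE))
  }
})

test_that("merging is transitive through connected components", {
  g <- testGrid(8, 8)
  train <- seq(0.2, 20, by = 0.2)
  ev <- rep(list(numeric()), nElectrodes(g))
  # chain A-B-C along a row: A-B and B-C adjacent (< 50 um), A-C 2 cols
  eA <- electrodeIndex(g, 4, 2); eB <- electrodeIndex(g, 4, 4)
  eC <- electrodeIndex(g, 4, 6)
  ev[[eA]] <- train; ev[[eB]] <- train + 0.001; ev[[eC]] <- train + 0.002
  ss <- identifySomas(ev, g)
  expect_identical(length(ss), 1L)
  expect_identical(somaMembers(ss)[[1]], sort(c(eA, eB, eC)))
  # position is the spike-count-weighted centroid
  pos <- electrodePositions(g, c(eA, eB, eC))
  expect_equal(somaTable(ss)$x_um, mean(pos[, 1]))
})

test_that("burst exclusion prevents cross-neuron merges", {
  g <- testGrid(8, 8)
  ev <- rep(list(numeric()), nElectrodes(g))
  e1 <- electrodeIndex(g, 4, 4); e2 <- electrodeIndex(g, 4, 5)
  # coincidences only inside the burst window [5, 6]
  burst <- seq(5.05, 5.95, by = 0.1)
  ev[[e1]] <- sort(c(burst, seq(0.5, 4.5, by = 0.5)))
  ev[[e2]] <- sort(c(burst + 0.001, seq(0.7, 4.7, by = 0.5) + 0.25))
  bw <- data.frame(start_s = 5, end_s = 6)
  # without exclusion the burst coincidences merge the electrodes
  expect_identical(length(identifySomas(ev, g)), 1L)
  # with exclusion no multi-electrode soma appears
  ssB <- identifySomas(ev, g, burstWindows = bw)
  expect_true(all(somaTable(ssB)$n_electrodes == 1L))
})

test_that("soma count matches planted neurons on a synthetic recording", {
  g <- ElectrodeGrid(24, 24, 10.52)
  cc <- (c(4, 12, 20) - 1) * 10.52       # >= 84 um spacing, 9 neurons
  pts <- expand.grid(x = cc, y = cc)
  neur <- lapply(seq_len(9), function(i)
    neuronSpec(pts$x[i], pts$y[i], baselineRateHz = 5))
  cfg <- simConfig(g, 2000, 20, neurons = neur, noiseSigmaUv = 3)
  sim <- simulateRecording(cfg, 31)
  det <- detectSpikesRecording(sim$recording)
  ss <- identifySomas(spikesByElectrode(det$spikes, g), g)
  expect_identical(length(ss), 9L)
  # every soma sits near one planted neuron
  tab <- somaTable(ss)
  for (i in seq_len(9)) {
    d <- sqrt((pts$x - tab$x_um[i])^2 + (pts$y - tab$y_um[i])^2)
    expect_lt(min(d), 15)
  }
  # spike trains are strictly increasing after deduplication
  for (tr in somaTrains(ss)) expect_true(all(diff(tr) > 0))
})

test_that("spiking electrodes without partners fall back to singletons", {
  g <- testGrid(8, 8)
  ev <- rep(list(numeric()), nElectrodes(g))
  ev[[10]] <- seq(1, 10)                 # 10 spikes, no partner anywhere
  ev[[40]] <- c(1, 2)                    # below the 5-spike floor
  ss <- identifySomas(ev, g)
  expect_identical(length(ss), 1L)
  expect_identical(somaMembers(ss)[[1]], 10L)
})
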