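test_that("synchronous counting handles the canonical cases", {
  tr <- seq(1, 50) * 0.9
  expect_identical(countSynchronous(tr, tr), 50L)
  expect_identical(countSynchronous(tr, tr + 0.2), 0L)
  # boundary inclusive (binary-exact offset: 125 ms window, 0.125 s shift)
  tre <- seq(1, 50) * 0.5
  expect_identical(countSynchronous(tre, tre + 0.125, windowMs = 125), 50L)
  expect_identical(countSynchronous(numeric(), tr), 0L)
  # worked example: 100 vs 50 spikes, 25 matches -> strength 1/3
  a <- seq_len(100); b <- seq_len(25) + 0.05
  b <- c(b, 1000 + seq_len(25))
  expect_identical(countSynchronous(a, b), 25L)
  expect_equal(connectionStrength(a, b), 25 / 75)
})

test_that("matched counting equals optimal bipartite matching (oracle)", {
  set.seed(17)
  for (r in 1:120) {
    a <- randTrain(sample(0:30, 1), span = 4)
    b <- randTrain(sample(0:30, 1), span = 4)
    expect_identical(countSynchronous(a, b, 100),
                     as.integer(oracleMatchCount(a, b, 0.1)))
  }
})

test_that("surrogates preserve the ISI multiset exactly", {
  # constant-ISI train maps to itself
  reg <- seq(0, 10, by = 0.5)
  set.seed(3)
  expect_equal(surrogateTrain(reg), reg)
  # any train: sorted ISIs identical, first spike and span preserved
  set.seed(4)
  for (r in 1:50) {
    tr <- randTrain(sample(2:100, 1), span = 30)
    s <- surrogateTrain(tr)
    expect_identical(length(s), length(tr))
    expect_equal(s[1], tr[1])
    expect_equal(max(s), max(tr))
    expect_equal(sort(diff(s)), sort(diff(tr)))
  }
  # short trains unchanged; reproducible under a fixed RNG state
  expect_identical(surrogateTrain(numeric()), numeric())
  expect_identical(surrogateTrain(5), 5)
  tr <- randTrain(20)
  set.seed(9); s1 <- surrogateTrain(tr)
  set.seed(9); s2 <- surrogateTrain(tr)
  expect_identical(s1, s2)
})

test_that("z-scores separate coupled pairs from the surrogate null", {
  set.seed(41)
  a <- poissonTrain(1.7, 60)
  z <- pairZscore(a, a + 0.010, seed = 6)
  expect_gte(z$z_score, 3)
  expect_false(z$degenerate)
  # degenerate path: regular trains make every surrogate identical
  reg <- seq(0, 30, by = 0.4)
  zd <- pairZscore(reg, reg + 0.05, seed = 6)
  expect_true(zd$degenerate)
  expect_identical(zd$surrogate_sd, 0)
  expect_identical(zd$z_score, 0)        # observed equals surrogate count
  expect_error(pairZscore(numeric(), reg), "empty")
  # substream reproducibility independent of other calls
  z1 <- pairZscore(a, a + 0.01, seed = 6, idA = 3, idB = 7)
  z2 <- pairZscore(a, a + 0.01, seed = 6, idA = 3, idB = 7)
  expect_identical(z1$z_score, z2$z_score)
})

test_that("the surrogate null is calibrated on independent trains", {
  set.seed(55)
  nsig <- 0L
  for (r in 1:40) {
    a <- poissonTrain(1, 120); b <- poissonTrain(1, 120)
    if (length(a) < 2 || length(b) < 2) next
    z <- pairZscore(a, b, seed = 1000 + r)
    if (is.finite(z$z_score) && z$z_score >= 3) nsig <- nsig + 1L
  }
  expect_lte(nsig / 40, 0.1)
})

test_that("the connection graph and degrees match a brute-force recount", {
  set.seed(12)
  n <- 8
  pr <- t(combn(seq_len(n), 2))
  pairs <- data.frame(soma_a = pr[, 1], soma_b = pr[, 2],
                      sync_count = 0L, surrogate_mean = 0,
                      surrogate_sd = 1, z_score = rnorm(nrow(pr), 2, 2))
  pairs$connected <- pairs$z_score >= 3
  gr <- buildGraph(pairs, zThresh = 3, nNodes = n)
  # brute force degree recount
  deg <- integer(n)
  for (k in which(pairs$z_score >= 3)) {
    deg[pairs$soma_a[k]] <- deg[pairs$soma_a[k]] + 1L
    deg[pairs$soma_b[k]] <- deg[pairs$soma_b[k]] + 1L
  }
  expect_identical(gr$degrees, deg)
  expect_equal(gr$meanDegree, 2 * gr$nEdges / n)
  # no connections -> edgeless graph
  pairs0 <- pairs; pairs0$z_score <- 0
  expect_identical(buildGraph(pairs0, nNodes = n)$degrees, integer(n))
  # complete graph on 5 nodes
  pr5 <- t(combn(1:5, 2))
  pairs5 <- data.frame(soma_a = pr5[, 1], soma_b = pr5[, 2],
                       sync_count = 1L, surrogate_mean = 0,
                       surrogate_sd = 1, z_score = 10, connected = TRUE)
  expect_identical(buildGraph(pairs5)$degrees, rep(4L, 5))
  expect_error(buildGraph(rbind(pairs5, pairs5[1, ])), "duplicate")
})

test_that("connection strength normalizes by the pair mean spike count", {
  tr <- seq_len(40) / 2
  expect_equal(connectionStrength(tr, tr), 1)
  expect_equal(connectionStrength(tr, tr + 500), 0)
  expect_error(connectionStrength(numeric(), numeric()), "undefined")
  # bounded by [0, 2]
  set.seed(14)
  for (r in 1:20) {
    s <- connectionStrength(randTrain(30, 10), randTrain(10, 10))
    expect_gte(s, 0); expect_lte(s, 2)
  }
})

test_that("region strength summaries cover within and between scopes", {
  # all pairs identical trains -> all summaries equal 1
  tr <- seq_len(30)
  trains <- list(tr, tr, tr, tr)
  regs <- c("A", "A", "B", "B")
  rs <- regionStrengths(trains, regs)
  expect_setequal(rs$scope, c("within", "between"))
  expect_true(all(abs(rs$mean_strength - 1) < 1e-12))
  expect_identical(rs$n_pairs[rs$scope == "between"], 4L)
  # single region: only one within summary
  rs1 <- regionStrengths(list(tr, tr + 0.01), c("A", "A"))
  expect_identical(nrow(rs1), 1L)
  # region with < 2 somas: within summary missing
  rs2 <- regionStrengths(list(tr, tr, tr), c("A", "A", "B"))
  expect_true(is.na(rs2$mean_strength[rs2$region_a == "B" &
                                        rs2$scope == "within"]))
  expect_error(regionStrengths(list(tr), c("A", "B")), "label")
})

test_that("between-region strength rises with planted coupling", {
  g <- testGrid(10, 4)
  strength <- function(p, seed = 19) {
    neur <- list(neuronSpec(10.52, 10.52, baselineRateHz = 1),
                 neuronSpec(21.04, 21.04, baselineRateHz = 1),
                 neuronSpec(10.52, 73.64, baselineRateHz = 1),
                 neuronSpec(21.04, 84.16, baselineRateHz = 1))
    cps <- list(couplingSpec(1, 3, p, 20, 5), couplingSpec(2, 4, p, 20, 5))
    cfg <- simConfig(g, 2000, 120, neurons = neur, couplings = cps,
                     noiseSigmaUv = 0, regionSplitRow = 5L)
    sim <- simulateAssembloidRecording(cfg, seed)
    tr <- truthTrains(sim$truth)
    regs <- vapply(sim$truth@neurons, function(x) x$region, character(1))
    rs <- regionStrengths(tr, regs)
    rs$mean_strength[rs$scope == "between"]
  }
  s <- c(strength(0.1), strength(0.3), strength(0.6))
  expect_true(all(diff(s) > 0))
})
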