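## Synthetic MEA recording generator with full ground truth. Emulates
## the statistical structure of organoid/assembloid field-potential
## recordings: per-electrode Gaussian noise and slow drift, planted
## neurons with Gaussian spatial spike footprints and Poisson/burst
## firing, propagating oscillation events with a chosen wavefront speed
## and extent, per-band spatial amplitude fields, and two-region
## layouts with tunable inter-region spike coupling. Output is a pure
## function of (config, seed).

seedOffset <- function(seed, k) {
  as.integer((as.numeric(seed) + as.numeric(k)) %% 2147483629)
}

#' Planted neuron specification
#'
#' @param xUm,yUm soma position in um (inside the grid bounding box).
#' @param footprintSigmaUm spatial decay scale of the spike amplitude
#'   (Gaussian, um).
#' @param peakAmpUv spike peak amplitude at the soma position (uV, > 0).
#' @param baselineRateHz Poisson firing rate outside bursts (Hz, >= 0).
#' @param burstGain multiplicative rate factor inside network burst
#'   windows.
#' @param region optional region label (assembloids).
#' @param seed optional per-neuron seed tag; neurons with the same tag
#'   draw the same spike times under the same generator seed, making the
#'   voltage superposition property testable.
#' @return A `NeuronSpec` list.
#' @export
neuronSpec <- function(xUm, yUm, footprintSigmaUm = 15, peakAmpUv = 18,
                       baselineRateHz = 2, burstGain = 5,
                       region = NA_character_, seed = NULL) {
  if (peakAmpUv <= 0) stop("peakAmpUv must be > 0")
  if (baselineRateHz < 0) stop("baselineRateHz must be >= 0")
  if (footprintSigmaUm <= 0) stop("footprintSigmaUm must be > 0")
  structure(list(xUm = xUm, yUm = yUm, footprintSigmaUm = footprintSigmaUm,
                 peakAmpUv = peakAmpUv, baselineRateHz = baselineRateHz,
                 burstGain = burstGain, region = region, seed = seed),
            class = "NeuronSpec")
}

#' Planted propagating oscillation specification
#'
#' A slow oscillation sweeping the array: each electrode in the extent
#' mask plays the same carrier-times-Hann waveform, delayed by its
#' distance from the wavefront origin divided by the wavefront speed.
#' Because the waveform is a pure translation per electrode, the planted
#' per-electrode peak time is exactly `onset(e) + wavePeakOffset(...)`.
#'
#' @param onsetS wave onset time at the earliest electrode (s).
#' @param mode "plane" (wavefront sweeping along `direction`) or
#'   "radial" (expanding from `origin`).
#' @param origin (x, y) in um, used by radial mode.
#' @param direction length-2 vector, plane-wave direction (normalized
#'   internally).
#' @param speedUmPerS wavefront speed (um/s, > 0).
#' @param extentMask integer electrode indices reached by the wave;
#'   NULL means all electrodes.
#' @param carrierFreqHz oscillation frequency (Hz).
#' @param ampUv oscillation amplitude (uV, > 0).
#' @param durationS per-electrode oscillation duration (s).
#' @return A `WaveSpec` list.
#' @export
waveSpec <- function(onsetS, mode = c("plane", "radial"), origin = c(0, 0),
                     direction = c(1, 0), speedUmPerS, extentMask = NULL,
                     carrierFreqHz = 10, ampUv = 50, durationS = 0.15) {
  mode <- match.arg(mode)
  if (speedUmPerS <= 0) stop("speedUmPerS must be > 0")
  if (ampUv <= 0) stop("ampUv must be > 0")
  if (!is.null(extentMask) && length(extentMask) == 0L)
    stop("extentMask must be non-empty (or NULL for all electrodes)")
  structure(list(onsetS = onsetS, mode = mode, origin = as.numeric(origin),
                 direction = as.numeric(direction),
                 speedUmPerS = speedUmPerS, extentMask = extentMask,
                 carrierFreqHz = carrierFreqHz, ampUv = ampUv,
                 durationS = durationS),
            class = "WaveSpec")
}

#' Planted frequency-band spatial field specification
#'
#' Per-band spatial amplitude maps over electrodes, realized at
#' generation time as band-limited Gaussian noise carriers (one per
#' band, unit RMS) multiplied by the per-band amplitude map. The
#' planted partition `clusterLabels` that generated the maps is the
#' recovery oracle for spatial clustering.
#'
#' @param maps numeric matrix, electrodes x bands (non-negative);
#'   column names must match band names.
#' @param clusterLabels integer planted region label per electrode.
#' @param bands band definition data.frame (see [bandDefinitions()]).
#' @return A `BandFieldSpec` list.
#' @export
bandFieldSpec <- function(maps, clusterLabels, bands = bandDefinitions()) {
  maps <- as.matrix(maps)
  if (any(maps < 0)) stop("band amplitude maps must be non-negative")
  if (nrow(maps) != length(clusterLabels))
    stop("clusterLabels must cover all electrodes in maps")
  if (is.null(colnames(maps))) colnames(maps) <- bands$name[seq_len(ncol(maps))]
  if (!all(colnames(maps) %in% bands$name))
    stop("map columns must be named after bands")
  structure(list(maps = maps, clusterLabels = as.integer(clusterLabels),
                 bands = bands),
            class = "BandFieldSpec")
}

#' Directed spike coupling specification
#'
#' @param pre,post neuron indices (into the config's neuron list).
#' @param couplingProb probability in `[0, 1]` that a pre spike triggers
#'   a post spike.
#' @param delayMs mean transmission delay in ms (>= 0, < 100).
#' @param jitterMs delay SD in ms.
#' @return A `CouplingSpec` list.
#' @export
couplingSpec <- function(pre, post, couplingProb, delayMs, jitterMs = 0) {
  if (couplingProb < 0 || couplingProb > 1)
    stop("couplingProb must be in [0, 1]")
  if (delayMs < 0) stop("delayMs must be >= 0")
  structure(list(pre = as.integer(pre), post = as.integer(post),
                 couplingProb = couplingProb, delayMs = delayMs,
                 jitterMs = jitterMs),
            class = "CouplingSpec")
}

#' Generator configuration
#'
#' Collects everything [simulateRecording()] needs. Defaults describe
#' the baseline synthetic study conditions: 3 uV Gaussian electrode
#' noise, no drift, no bursts.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param fs sampling rate (Hz).
#' @param durationS recording duration (s).
#' @param neurons list of [neuronSpec()].
#' @param waves list of [waveSpec()].
#' @param bandFields a [bandFieldSpec()] or NULL.
#' @param couplings list of [couplingSpec()] (assembloids).
#' @param burstWindows data.frame with `start_s`, `end_s` columns of
#'   network burst windows (shared rate-gain windows), or NULL.
#' @param noiseSigmaUv per-sample Gaussian noise SD (uV).
#' @param driftSlopeUvPerS linear drift slope (uV/s), per electrode.
#' @param driftSineAmpUv amplitude of a slow sinusoidal drift component
#'   (uV); phase varies across electrodes.
#' @param driftSineHz slow drift frequency (< 0.2 Hz recommended).
#' @param regionSplitRow assembloids: rows `1..regionSplitRow` belong to
#'   the first region, the rest to the second.
#' @param regionNames length-2 region names.
#' @return A `SimConfig` list.
#' @export
simConfig <- function(grid, fs, durationS, neurons = list(), waves = list(),
                      bandFields = NULL, couplings = list(),
                      burstWindows = NULL, noiseSigmaUv = 3,
                      driftSlopeUvPerS = 0, driftSineAmpUv = 0,
                      driftSineHz = 0.1, regionSplitRow = NULL,
                      regionNames = c("striatum", "midbrain")) {
  if (!is(grid, "ElectrodeGrid")) stop("grid must be an ElectrodeGrid")
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0")
  if (!is.finite(durationS) || durationS <= 0) stop("durationS must be > 0")
  xmax <- (grid@nCols - 1) * grid@pitchUm
  ymax <- (grid@nRows - 1) * grid@pitchUm
  for (nu in neurons) {
    if (nu$xUm < 0 || nu$xUm > xmax || nu$yUm < 0 || nu$yUm > ymax)
      stop("neuron outside grid bounding box")
  }
  if (is.null(burstWindows))
    burstWindows <- data.frame(start_s = numeric(), end_s = numeric())
  structure(list(grid = grid, fs = fs, durationS = durationS,
                 neurons = neurons, waves = waves, bandFields = bandFields,
                 couplings = couplings, burstWindows = burstWindows,
                 noiseSigmaUv = noiseSigmaUv,
                 driftSlopeUvPerS = driftSlopeUvPerS,
                 driftSineAmpUv = driftSineAmpUv,
                 driftSineHz = driftSineHz,
                 regionSplitRow = regionSplitRow,
                 regionNames = regionNames),
            class = "SimConfig")
}

#' Biphasic spike template
#'
#' Difference-of-Gaussians biphasic waveform (negative then positive
#' lobe, total width about 1.2 ms) sampled at `fs`, normalized so the
#' negative peak equals -1 exactly at the center sample.
#'
#' @param fs sampling rate (Hz).
#' @return Numeric vector of length `2 * round(fs / 1000) + 1` (at
#'   least 3).
#' @export
spikeTemplate <- function(fs) {
  half <- max(1L, round(0.001 * fs))
  t <- (-half:half) / fs
  w <- -exp(-t^2 / (2 * 0.00018^2)) +
    0.45 * exp(-(t - 0.00035)^2 / (2 * 0.0003^2))
  w / abs(min(w))
}

## Sample-aligned spike times for one neuron: inhomogeneous Poisson with
## rate r outside bursts and r * gain inside.
drawSpikeTimes <- function(rateHz, burstGain, burstWindows, durationS, fs,
                           localSeed) {
  set.seed(localSeed)
  bounds <- sort(unique(c(0, durationS,
                          pmin(pmax(burstWindows$start_s, 0), durationS),
                          pmin(pmax(burstWindows$end_s, 0), durationS))))
  times <- numeric()
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    inBurst <- any(burstWindows$start_s <= a & burstWindows$end_s >= b)
    r <- rateHz * if (inBurst) burstGain else 1
    k <- stats::rpois(1L, r * (b - a))
    if (k > 0) times <- c(times, stats::runif(k, a, b))
  }
  n <- round(durationS * fs)
  idx <- unique(sort(pmin(round(times * fs), n - 1L)))
  idx / fs
}

## One neuron's spike contribution: affected electrodes, per-electrode
## amplitude scale, affected sample columns, and the accumulated
## template values per column. Contributions below 0.5 uV are truncated
## spatially. Returned rather than applied so the caller can add it to
## the voltage matrix in place (no full-matrix copies).
neuronContribution <- function(grid, spec, spikeTimes, fs, template, n) {
  if (!length(spikeTimes)) return(NULL)
  pos <- electrodePositions(grid)
  d2 <- (pos[, 1] - spec$xUm)^2 + (pos[, 2] - spec$yUm)^2
  amp <- spec$peakAmpUv * exp(-d2 / (2 * spec$footprintSigmaUm^2))
  sel <- which(amp >= 0.5)
  if (!length(sel)) return(NULL)
  half <- (length(template) - 1L) %/% 2L
  s0 <- round(spikeTimes * fs)              # 0-based center samples
  offs <- -half:half
  idxAll <- rep(s0, each = length(offs)) + rep(offs, times = length(s0)) + 1L
  tmplAll <- rep(template, times = length(s0))
  ok <- idxAll >= 1L & idxAll <= n
  agg <- rowsum(tmplAll[ok], idxAll[ok])    # accumulate overlaps
  list(electrodes = sel, amps = amp[sel],
       cols = as.integer(rownames(agg)), vals = agg[, 1L])
}

#' Per-electrode onset times of a planted wave
#'
#' @param wave a [waveSpec()].
#' @param grid the [ElectrodeGrid-class].
#' @param electrodes electrode indices; default the wave's extent mask
#'   (or all electrodes).
#' @return Named numeric vector of onset times (s), names = electrode
#'   indices.
#' @export
waveOnsetTimes <- function(wave, grid,
                           electrodes = NULL) {
  if (is.null(electrodes))
    electrodes <- if (is.null(wave$extentMask)) seq_len(nElectrodes(grid))
                  else wave$extentMask
  pos <- electrodePositions(grid, electrodes)
  if (wave$mode == "plane") {
    dir <- wave$direction / sqrt(sum(wave$direction^2))
    proj <- pos[, 1] * dir[1] + pos[, 2] * dir[2]
    on <- wave$onsetS + (proj - min(proj)) / wave$speedUmPerS
  } else {
    d <- sqrt((pos[, 1] - wave$origin[1])^2 + (pos[, 2] - wave$origin[2])^2)
    on <- wave$onsetS + d / wave$speedUmPerS
  }
  names(on) <- electrodes
  on
}

## Sampled per-electrode wave waveform (identical for every electrode;
## the wave is a pure translation).
waveWaveform <- function(wave, fs) {
  nW <- max(1L, round(wave$durationS * fs))
  tau <- (seq_len(nW) - 1L) / fs
  wave$ampUv * sin(2 * pi * wave$carrierFreqHz * tau) *
    sin(pi * tau / wave$durationS)^2
}

#' Peak-time offset of a planted wave
#'
#' Time from an electrode's wave onset to its absolute voltage peak, on
#' the sample grid. Identical for every electrode because the wave is a
#' pure translation, so the planted peak time of electrode e is
#' `waveOnsetTimes(...)[e] + wavePeakOffset(...)`.
#'
#' @param wave a [waveSpec()].
#' @param fs sampling rate (Hz).
#' @return Offset in seconds.
#' @export
wavePeakOffset <- function(wave, fs) {
  wv <- waveWaveform(wave, fs)
  (which.max(abs(wv)) - 1L) / fs
}

## Band-limited unit-RMS carriers, one per planted band field.
bandFieldCarriers <- function(bf, n, fs, seed) {
  out <- vector("list", ncol(bf$maps))
  for (b in seq_len(ncol(bf$maps))) {
    nm <- colnames(bf$maps)[b]
    def <- bf$bands[bf$bands$name == nm, ]
    set.seed(seedOffset(seed, 3000 + b))
    carrier <- stats::rnorm(n)
    spec <- filterSpec("bandpass", c(def$lo_hz, def$hi_hz))
    carrier <- zeroPhaseFilter(carrier, firCoefficients(spec, fs))
    out[[b]] <- carrier / sqrt(mean(carrier^2))     # unit RMS
  }
  out
}

.simulateCore <- function(config, seed, assembloid = FALSE) {
  if (!inherits(config, "SimConfig")) stop("config must be a simConfig()")
  grid <- config$grid; fs <- config$fs
  n <- round(config$durationS * fs)
  if (n < 1L) stop("durationS too short for fs")
  nE <- nElectrodes(grid)
  seed <- as.integer(seed)

  ## region labels (assembloid layout: split by row)
  labels <- character()
  if (assembloid) {
    sr <- config$regionSplitRow
    if (is.null(sr) || sr < 1L || sr >= grid@nRows)
      stop("assembloid config needs regionSplitRow in [1, nRows - 1]")
    rows <- electrodeRowCol(grid, seq_len(nE))[, "row"]
    labels <- ifelse(rows <= sr, config$regionNames[1], config$regionNames[2])
    for (i in seq_along(config$neurons)) {
      nu <- config$neurons[[i]]
      reg <- if (nu$yUm <= (sr - 1) * grid@pitchUm + grid@pitchUm / 2)
        config$regionNames[1] else config$regionNames[2]
      if (is.na(nu$region)) config$neurons[[i]]$region <- reg
      else if (nu$region != reg)
        stop("neuron ", i, " region label conflicts with its position")
    }
  }

  ## noise (dim<- avoids a second full-size copy)
  if (config$noiseSigmaUv > 0) {
    set.seed(seedOffset(seed, 1))
    V <- stats::rnorm(nE * n, 0, config$noiseSigmaUv)
    dim(V) <- c(nE, n)
  } else {
    V <- matrix(0, nE, n)
  }

  ## drift (row-wise, in place)
  t <- (seq_len(n) - 1L) / fs
  if (config$driftSlopeUvPerS != 0) {
    lin <- config$driftSlopeUvPerS * t
    for (e in seq_len(nE)) V[e, ] <- V[e, ] + lin
  }
  if (config$driftSineAmpUv != 0) {
    ph <- 2 * pi * seq_len(nE) / nE
    for (e in seq_len(nE))
      V[e, ] <- V[e, ] + config$driftSineAmpUv *
        sin(2 * pi * config$driftSineHz * t + ph[e])
  }

  ## neuron spike trains
  trains <- vector("list", length(config$neurons))
  for (i in seq_along(config$neurons)) {
    nu <- config$neurons[[i]]
    tag <- if (is.null(nu$seed)) i else nu$seed
    trains[[i]] <- drawSpikeTimes(nu$baselineRateHz, nu$burstGain,
                                  config$burstWindows, config$durationS, fs,
                                  seedOffset(seed, 7919 * tag))
  }

  ## coupled (triggered) spikes
  parent <- list()
  triggered <- vector("list", length(config$neurons))
  for (j in seq_along(config$couplings)) {
    cp <- config$couplings[[j]]
    preT <- trains[[cp$pre]]
    if (!length(preT)) next
    set.seed(seedOffset(seed, 104729 + 31 * j))
    keep <- stats::runif(length(preT)) < cp$couplingProb
    if (!any(keep)) next
    delays <- cp$delayMs / 1000 +
      if (cp$jitterMs > 0) stats::rnorm(sum(keep), 0, cp$jitterMs / 1000)
      else 0
    postT <- preT[keep] + delays
    postIdx <- round(postT * fs)
    ok <- postIdx >= 0L & postIdx <= n - 1L
    postT <- postIdx[ok] / fs
    if (!length(postT)) next
    triggered[[cp$post]] <- c(triggered[[cp$post]], postT)
    parent[[length(parent) + 1L]] <- data.frame(
      coupling = j, pre = cp$pre, post = cp$post,
      pre_time_s = preT[keep][ok], post_time_s = postT)
  }

  spikes <- list()
  for (i in seq_along(trains)) {
    base <- trains[[i]]
    trig <- triggered[[i]]
    if (length(trig)) {
      all <- sort(unique(c(base, trig)))
      spikes[[i]] <- data.frame(
        neuron = i, time_s = all,
        triggered = all %in% setdiff(trig, base))
      trains[[i]] <- all
    } else if (length(base)) {
      spikes[[i]] <- data.frame(neuron = i, time_s = base, triggered = FALSE)
    }
  }
  spikesDf <- if (length(spikes)) do.call(rbind, spikes)
    else data.frame(neuron = integer(), time_s = numeric(),
                    triggered = logical())

  ## spike waveforms on the array (applied in place)
  template <- spikeTemplate(fs)
  for (i in seq_along(config$neurons)) {
    cb <- neuronContribution(grid, config$neurons[[i]], trains[[i]], fs,
                             template, n)
    if (is.null(cb)) next
    for (j in seq_along(cb$electrodes))
      V[cb$electrodes[j], cb$cols] <- V[cb$electrodes[j], cb$cols] +
        cb$amps[j] * cb$vals
  }

  ## waves (each electrode plays a translated copy of one waveform)
  for (w in config$waves) {
    onsets <- waveOnsetTimes(w, grid)
    wv <- waveWaveform(w, fs)
    nW <- length(wv)
    el <- as.integer(names(onsets))
    o <- round(onsets * fs)                 # 0-based onset samples
    for (k in seq_along(el)) {
      i0 <- o[k] + 1L
      i1 <- min(i0 + nW - 1L, n)
      if (i1 < i0 || i0 > n) next
      j <- 1L:(i1 - i0 + 1L)
      if (i0 < 1L) { j <- j + (1L - i0); i0 <- 1L }
      V[el[k], i0:i1] <- V[el[k], i0:i1] + wv[j]
    }
  }

  ## band fields
  if (!is.null(config$bandFields)) {
    bf <- config$bandFields
    carriers <- bandFieldCarriers(bf, n, fs, seed)
    for (b in seq_along(carriers)) {
      act <- which(bf$maps[, b] > 0)
      for (e in act) V[e, ] <- V[e, ] + bf$maps[e, b] * carriers[[b]]
    }
  }

  rec <- MEARecording(V, fs = fs, grid = grid,
                      regionLabels = if (length(labels)) labels else NULL)
  truth <- new("GroundTruth",
               neurons = config$neurons, spikes = spikesDf,
               waves = config$waves, bandFields = config$bandFields,
               couplings = config$couplings,
               parentage = if (length(parent)) do.call(rbind, parent)
                 else data.frame(coupling = integer(), pre = integer(),
                                 post = integer(), pre_time_s = numeric(),
                                 post_time_s = numeric()),
               burstWindows = config$burstWindows,
               noiseSigmaUv = config$noiseSigmaUv)
  list(recording = rec, truth = truth)
}

#' Generate a synthetic recording with ground truth
#'
#' Voltage = Gaussian noise + drift + planted spike waveforms + planted
#' propagating oscillations + planted band fields. Every planted event
#' is recorded in the returned [GroundTruth-class]. Identical
#' `(config, seed)` gives bit-identical output.
#'
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return `list(recording = MEARecording, truth = GroundTruth)`.
#' @export
simulateRecording <- function(config, seed) {
  .simulateCore(config, seed, assembloid = FALSE)
}

#' Generate a synthetic two-region assembloid recording
#'
#' The grid is split at `regionSplitRow` into two labeled regions (e.g.
#' striatum above, midbrain below). Couplings across neurons produce
#' triggered spikes `delayMs` (+/- `jitterMs`) after pre spikes with
#' probability `couplingProb`; the ground truth records triggered-spike
#' parentage.
#'
#' @inheritParams simulateRecording
#' @return `list(recording = MEARecording, truth = GroundTruth)`; the
#'   recording carries per-electrode region labels.
#' @export
simulateAssembloidRecording <- function(config, seed) {
  .simulateCore(config, seed, assembloid = TRUE)
}

#' Spike trains of the ground truth, as a list
#'
#' @param truth a [GroundTruth-class].
#' @return List of numeric spike-time vectors, one per planted neuron.
#' @export
truthTrains <- function(truth) {
  out <- vector("list", length(truth@neurons))
  for (i in seq_along(out))
    out[[i]] <- truth@spikes$time_s[truth@spikes$neuron == i]
  out
}
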