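## End-to-end composition of the analysis stages, and the CSV result
## tables. Each stage is also available as a standalone function.

#' Run the full analysis pipeline on a recording
#'
#' Detrend, high-pass, detect spikes, detect network bursts, identify
#' somas, and (optionally) compute pairwise synchrony z-scores with the
#' connection graph, oscillation-event propagation endpoints, and band
#' power maps with clustering. Returns result tables matching the CSV
#' schemas of [writeResultTable()] output files.
#'
#' @param rec an [MEARecording-class].
#' @param seed integer seed for the surrogate and clustering stages.
#' @param segmentLen detrending segment length (samples).
#' @param highpassHz spike-detection high-pass corner (Hz).
#' @param threshMult spike threshold in sigmas.
#' @param sdMin waveform-SD noise rejection floor (uV); NA disables.
#' @param connectivity compute pairwise z-scores and the graph.
#' @param nSurr surrogates per pair.
#' @param windowMs synchrony window (ms).
#' @param zThresh connection threshold on z.
#' @param propagation compute oscillation events and endpoints.
#' @param ampMinUv propagating-electrode amplitude floor (uV).
#' @param bands compute band power maps and clustering.
#' @param k number of band clusters.
#' @return List of data.frames: `spikes`, `somas`, `edges`,
#'   `propagation`, `bandpower` (absent stages are NULL), plus the
#'   [SomaSet-class] as `somaSet`.
#' @export
runPipeline <- function(rec, seed = 1L, segmentLen = 500L, highpassHz = 100,
                        threshMult = 5.0, sdMin = NA, connectivity = TRUE,
                        nSurr = 100L, windowMs = 100, zThresh = 3,
                        propagation = TRUE, ampMinUv = 30, bands = FALSE,
                        k = 9L) {
  rec <- preprocessRecording(rec, segmentLen)
  det <- detectSpikesRecording(rec, highpassHz = highpassHz,
                               threshMult = threshMult, sdMin = sdMin)
  bursts <- detectNetworkBursts(det$spikes$time_s,
                                durationS = recordingDuration(rec))
  ev <- spikesByElectrode(det$spikes, rec@grid)
  somas <- identifySomas(ev, rec@grid, burstWindows = bursts)
  out <- list(spikes = det$spikes, somaSet = somas,
              somas = somaTable(somas), bursts = bursts,
              edges = NULL, degrees = NULL, propagation = NULL,
              bandpower = NULL)

  if (connectivity && length(somas) >= 2L) {
    pairs <- allPairZscores(somaTrains(somas), nSurr = nSurr,
                            windowMs = windowMs, seed = seed,
                            zThresh = zThresh)
    gr <- buildGraph(pairs, zThresh = zThresh, nNodes = length(somas))
    out$edges <- pairs
    out$degrees <- data.frame(soma_id = seq_len(length(somas)),
                              degree = gr$degrees)
  }

  if (propagation) {
    evs <- detectOscillationEvents(rec)
    rows <- list()
    for (i in seq_len(nrow(evs))) {
      e <- evs[i, ]
      pe <- propagatingElectrodes(rec, e, ampMinUv)
      if (!length(pe)) next
      pk <- peakTimeMap(rec, e, pe)
      rs <- recruitmentSeries(pk)
      pv <- propagationVelocity(rs)
      ar <- propagationArea(pe, rec@grid)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = e$event_id, onset_s = e$onset_s, offset_s = e$offset_s,
        n_propagating_electrodes = ar$nElectrodes, area_mm2 = ar$areaMm2,
        velocity = pv$velocity, mean_velocity = pv$meanVelocity,
        degenerate = pv$degenerate)
    }
    out$propagation <- if (length(rows)) do.call(rbind, rows)
      else data.frame(event_id = integer(), onset_s = numeric(),
                      offset_s = numeric(),
                      n_propagating_electrodes = integer(),
                      area_mm2 = numeric(), velocity = numeric(),
                      mean_velocity = numeric(), degenerate = logical())
  }

  if (bands) {
    inc <- usableElectrodes(rec)
    amp <- bandAmplitude(rec)
    z <- standardizeBandPower(amp, inc)
    cl <- clusterBands(z, k = min(k, length(inc)), seed = seed)
    bp <- data.frame(electrode = inc, amp[inc, , drop = FALSE])
    colnames(bp)[-1] <- colnames(amp)
    zdf <- as.data.frame(z)
    colnames(zdf) <- paste0(colnames(z), "_z")
    out$bandpower <- cbind(bp, zdf, cluster_id = cl$cluster)
  }
  out
}
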