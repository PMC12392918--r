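## Recovery metrics against the synthetic generator's ground truth.

#' Evaluate spike detection against planted ground truth
#'
#' Recall: fraction of planted spikes with at least one detected event
#' within `toleranceS` on an electrode within `radiusUm` of the planted
#' neuron. Precision: fraction of detected events within `toleranceS`
#' of a planted spike of a neuron within `radiusUm` of the event's
#' electrode.
#'
#' @param truth a [GroundTruth-class].
#' @param spikes spike table from [detectSpikesRecording()].
#' @param grid the [ElectrodeGrid-class].
#' @param toleranceS time matching tolerance (s, default 1 ms).
#' @param radiusUm spatial association radius (um).
#' @return List with `recall`, `precision`, `nPlanted`, `nDetected`.
#' @export
evaluateSpikeDetection <- function(truth, spikes, grid, toleranceS = 0.001,
                                   radiusUm = 30) {
  pos <- electrodePositions(grid)
  nPos <- t(vapply(truth@neurons, function(nu) c(nu$xUm, nu$yUm), numeric(2)))
  trains <- truthTrains(truth)
  nPlanted <- sum(lengths(trains))
  nDetected <- nrow(spikes)
  if (nPlanted == 0L || nDetected == 0L)
    return(list(recall = NA_real_, precision = NA_real_,
                nPlanted = nPlanted, nDetected = nDetected))
  near <- function(t0, times) {
    if (!length(times)) return(FALSE)
    i <- findInterval(t0, times)
    lo <- if (i >= 1L) abs(t0 - times[i]) else Inf
    hi <- if (i < length(times)) abs(times[i + 1L] - t0) else Inf
    min(lo, hi) <= toleranceS
  }
  ## recall
  hits <- 0L
  detByEl <- split(spikes$time_s, spikes$electrode)
  for (k in seq_along(trains)) {
    if (!length(trains[[k]])) next
    d <- sqrt((pos[, 1] - nPos[k, 1])^2 + (pos[, 2] - nPos[k, 2])^2)
    els <- as.character(which(d <= radiusUm))
    dt <- sort(unlist(detByEl[intersect(els, names(detByEl))],
                      use.names = FALSE))
    for (t0 in trains[[k]]) if (near(t0, dt)) hits <- hits + 1L
  }
  ## precision
  tp <- 0L
  neuronsNearEl <- vector("list", nElectrodes(grid))
  activeEl <- unique(spikes$electrode)
  for (e in activeEl) {
    d <- sqrt((nPos[, 1] - pos[e, 1])^2 + (nPos[, 2] - pos[e, 2])^2)
    ks <- which(d <= radiusUm)
    if (length(ks))
      neuronsNearEl[[e]] <- sort(unlist(trains[ks], use.names = FALSE))
  }
  for (r in seq_len(nDetected)) {
    tt <- neuronsNearEl[[spikes$electrode[r]]]
    if (!is.null(tt) && near(spikes$time_s[r], tt)) tp <- tp + 1L
  }
  list(recall = hits / nPlanted, precision = tp / nDetected,
       nPlanted = nPlanted, nDetected = nDetected)
}

#' Jaccard index of two index sets
#'
#' @param a,b integer vectors.
#' @return `|a intersect b| / |a union b|` (1 when both empty).
#' @export
jaccardIndex <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
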