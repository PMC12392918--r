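## Spike detection per electrode: +/- 5 sigma threshold on the 100 Hz
## high-passed trace, one event per supra-threshold excursion, 41-sample
## waveform extraction, waveform-SD noise rejection.

#' Estimate baseline noise SD of a high-passed trace
#'
#' If a quiescent interval is supplied, sigma is the plain SD over that
#' interval; otherwise the robust estimate `median(|x|) / 0.6745`.
#'
#' @param x high-pass filtered voltage vector (uV).
#' @param quiescent optional `c(start_s, end_s)` interval; requires `fs`.
#' @param fs sampling rate (Hz), needed only with `quiescent`.
#' @return Sigma in uV.
#' @export
estimateSigma <- function(x, quiescent = NULL, fs = NULL) {
  if (is.null(quiescent))
    return(stats::median(abs(x)) / 0.6745)
  if (is.null(fs)) stop("fs is required with a quiescent interval")
  i0 <- max(1L, floor(quiescent[1] * fs) + 1L)
  i1 <- min(length(x), ceiling(quiescent[2] * fs))
  if (i1 < i0) stop("quiescent interval is empty")
  stats::sd(x[i0:i1])
}

#' Detect spikes on one electrode trace
#'
#' Finds supra-threshold excursions `|x| >= threshMult * sigma` and
#' reports one event per excursion at its absolute-value peak (earliest
#' sample on ties). Each event carries the signed peak amplitude and a
#' `2 * halfWindow + 1` sample waveform (zero-padded at trace edges).
#' Events closer than `refractorySamples` are merged, keeping the
#' larger-amplitude one.
#'
#' @param x high-pass filtered voltage vector (uV).
#' @param sigma baseline noise SD (uV, > 0).
#' @param threshMult threshold multiplier (default 5.0).
#' @param halfWindow waveform half length in samples (default 20, i.e.
#'   41-sample waveforms).
#' @param refractorySamples minimum event separation in samples (0 =
#'   excursion grouping only).
#' @return `list(events = data.frame(sample, amplitude_uV), waveforms =
#'   matrix)`; `sample` is 1-based, events sorted by time, waveforms one
#'   row per event.
#' @export
detectSpikes <- function(x, sigma, threshMult = 5.0, halfWindow = 20L,
                         refractorySamples = 0L) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0 (degenerate input cannot be thresholded)")
  thr <- threshMult * sigma
  wlen <- 2L * halfWindow + 1L
  empty <- list(events = data.frame(sample = integer(),
                                    amplitude_uV = numeric()),
                waveforms = matrix(numeric(), 0L, wlen))
  idx <- which(abs(x) >= thr)
  if (!length(idx)) return(empty)
  grp <- cumsum(c(1L, diff(idx) > 1L))
  peaks <- vapply(split(idx, grp), function(ii) ii[which.max(abs(x[ii]))],
                  integer(1))
  peaks <- unname(sort(peaks))
  if (refractorySamples > 0L && length(peaks) > 1L) {
    keep <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- keep[length(keep)]
      if (p - last < refractorySamples) {
        if (abs(x[p]) > abs(x[last])) keep[length(keep)] <- p
      } else keep <- c(keep, p)
    }
    peaks <- keep
  }
  wf <- matrix(0, length(peaks), wlen)
  n <- length(x)
  for (k in seq_along(peaks)) {
    ii <- (peaks[k] - halfWindow):(peaks[k] + halfWindow)
    ok <- ii >= 1L & ii <= n
    wf[k, ok] <- x[ii[ok]]
  }
  list(events = data.frame(sample = peaks, amplitude_uV = x[peaks]),
       waveforms = wf)
}

#' Reject noise waveforms by waveform SD
#'
#' Keeps events whose 41-sample waveform SD (uV) is at least `sdMin`
#' (default 13, the noise-rejection floor for spike waveforms).
#'
#' @param det result of [detectSpikes()] (or the recording-level spike
#'   table with a `waveforms` attribute from [detectSpikesRecording()]).
#' @param sdMin minimum waveform SD in uV.
#' @return Same structure with sub-threshold-SD events removed.
#' @export
rejectNoiseWaveforms <- function(det, sdMin = 13.0) {
  wf <- det$waveforms
  if (nrow(wf) == 0L) return(det)
  keep <- apply(wf, 1L, stats::sd) >= sdMin
  det$events <- det$events[keep, , drop = FALSE]
  rownames(det$events) <- NULL
  det$waveforms <- wf[keep, , drop = FALSE]
  det
}

#' Detect spikes on every electrode of a recording
#'
#' High-passes the recording (unless `highpassHz` is NULL, for traces
#' already filtered), estimates sigma per electrode, detects spikes and
#' optionally applies waveform noise rejection.
#'
#' @param rec an [MEARecording-class].
#' @param highpassHz high-pass corner (Hz) applied before detection;
#'   NULL to skip filtering.
#' @param threshMult,halfWindow,refractorySamples see [detectSpikes()].
#' @param sdMin waveform-SD rejection floor (uV); NA disables rejection.
#' @return `list(spikes = data.frame(electrode, sample_index, time_s,
#'   amplitude_uV), waveforms = matrix, sigma = numeric)`.
#' @export
detectSpikesRecording <- function(rec, highpassHz = 100, threshMult = 5.0,
                                  halfWindow = 20L, refractorySamples = 0L,
                                  sdMin = NA) {
  v <- rec@voltage
  if (!is.null(highpassHz)) {
    spec <- filterSpec("highpass", highpassHz)
    v <- zeroPhaseFilter(v, firCoefficients(spec, rec@fs))
  }
  nE <- nrow(v)
  out <- vector("list", nE)
  wfs <- vector("list", nE)
  sig <- numeric(nE)
  for (e in seq_len(nE)) {
    sig[e] <- estimateSigma(v[e, ])
    if (sig[e] <= 0) next
    det <- detectSpikes(v[e, ], sig[e], threshMult, halfWindow,
                        refractorySamples)
    if (!is.na(sdMin)) det <- rejectNoiseWaveforms(det, sdMin)
    if (nrow(det$events)) {
      out[[e]] <- data.frame(electrode = e,
                             sample_index = det$events$sample,
                             time_s = (det$events$sample - 1L) / rec@fs,
                             amplitude_uV = det$events$amplitude_uV)
      wfs[[e]] <- det$waveforms
    }
  }
  keep <- !vapply(out, is.null, logical(1))
  spikes <- if (any(keep)) do.call(rbind, out[keep])
    else data.frame(electrode = integer(), sample_index = integer(),
                    time_s = numeric(), amplitude_uV = numeric())
  rownames(spikes) <- NULL
  list(spikes = spikes,
       waveforms = if (any(keep)) do.call(rbind, wfs[keep])
         else matrix(numeric(), 0L, 2L * halfWindow + 1L),
       sigma = sig)
}

#' Detect network bursts from pooled spike times
#'
#' Bins the pooled population spike times (`binS`), seeds bursts at bins
#' whose count exceeds `mean + k * SD`, extends each burst across
#' contiguous above-mean bins, and discards windows shorter than
#' `minBins` bins.
#'
#' @param times pooled spike times (s), any order.
#' @param binS bin width (s).
#' @param k threshold in SDs above the mean bin count.
#' @param minBins minimum burst length in bins.
#' @param durationS optional recording duration; defaults to the last
#'   spike time.
#' @return data.frame with columns `start_s`, `end_s` (disjoint,
#'   sorted).
#' @export
detectNetworkBursts <- function(times, binS = 0.1, k = 3.0, minBins = 2L,
                                durationS = NULL) {
  empty <- data.frame(start_s = numeric(), end_s = numeric())
  if (!length(times)) return(empty)
  times <- sort(times)
  if (is.null(durationS)) durationS <- times[length(times)]
  nb <- max(1L, ceiling(durationS / binS))
  cnt <- tabulate(pmin(floor(times / binS) + 1L, nb), nbins = nb)
  mu <- mean(cnt); sdv <- stats::sd(cnt)
  if (!is.finite(sdv) || sdv == 0) return(empty)
  seeds <- cnt > mu + k * sdv
  if (!any(seeds)) return(empty)
  above <- cnt > mu
  ## burst = maximal run of above-mean bins containing at least one seed
  grp <- cumsum(c(1L, diff(above) != 0L))
  windows <- empty
  for (g in unique(grp[above])) {
    ii <- which(grp == g)
    if (!any(seeds[ii])) next
    if (length(ii) < minBins) next
    windows <- rbind(windows,
                     data.frame(start_s = (ii[1] - 1L) * binS,
                                end_s = ii[length(ii)] * binS))
  }
  rownames(windows) <- NULL
  windows
}

## TRUE for times inside any [start, end] window.
inWindows <- function(times, windows) {
  if (!nrow(windows) || !length(times)) return(rep(FALSE, length(times)))
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(windows)))
    out <- out | (times >= windows$start_s[i] & times <= windows$end_s[i])
  out
}
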