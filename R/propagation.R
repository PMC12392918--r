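## Propagation endpoints: detect network-wide oscillation events, map
## per-electrode peak times, and derive propagation velocity (rate of
## electrode recruitment) and propagation area (spatial extent of
## propagating electrodes).

#' Detect network-wide oscillation events
#'
#' Builds the population trace `mean(|voltage|)` across electrodes,
#' smooths it with a moving average of width `smoothS`, and marks events
#' where it exceeds `median + k * MAD` of the whole trace for at least
#' `minDurS`. Each event window is extended outward to the flanking
#' crossings of the baseline median.
#'
#' @param rec a detrended [MEARecording-class].
#' @param smoothS moving-average width (s).
#' @param k threshold in MADs above the median.
#' @param minDurS minimum event duration (s).
#' @return data.frame with columns `event_id`, `onset_s`, `offset_s`.
#' @export
detectOscillationEvents <- function(rec, smoothS = 0.05, k = 4.0,
                                    minDurS = 0.2) {
  n <- ncol(rec@voltage)
  if (n < 2L) stop("recording too short for event detection")
  pop <- colMeans(abs(rec@voltage))
  w <- max(1L, round(smoothS * rec@fs))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    pop <- stats::filter(pop, kern, sides = 2)
    pop[is.na(pop)] <- mean(pop, na.rm = TRUE)
    pop <- as.numeric(pop)
  }
  med <- stats::median(pop)
  madv <- stats::mad(pop)
  empty <- data.frame(event_id = integer(), onset_s = numeric(),
                      offset_s = numeric())
  if (madv == 0) return(empty)
  thr <- med + k * madv
  above <- pop > thr
  if (!any(above)) return(empty)
  grp <- cumsum(c(1L, diff(above) != 0L))
  rows <- list()
  minLen <- minDurS * rec@fs
  belowMed <- pop <= med
  for (g in unique(grp[above])) {
    ii <- which(grp == g)
    if (length(ii) < minLen) next
    ## extend to flanking sub-median crossings
    s <- ii[1]
    while (s > 1L && !belowMed[s - 1L]) s <- s - 1L
    e <- ii[length(ii)]
    while (e < n && !belowMed[e + 1L]) e <- e + 1L
    rows[[length(rows) + 1L]] <- c(s, e)
  }
  if (!length(rows)) return(empty)
  m <- do.call(rbind, rows)
  ## merge windows that became overlapping after extension
  keep <- list(m[1, ])
  if (nrow(m) > 1L)
    for (r in 2:nrow(m)) {
      last <- keep[[length(keep)]]
      if (m[r, 1] <= last[2]) keep[[length(keep)]] <- c(last[1], max(last[2], m[r, 2]))
      else keep[[length(keep) + 1L]] <- m[r, ]
    }
  m <- do.call(rbind, keep)
  data.frame(event_id = seq_len(nrow(m)),
             onset_s = (m[, 1] - 1L) / rec@fs,
             offset_s = (m[, 2] - 1L) / rec@fs)
}

#' Propagating electrodes of an oscillation event
#'
#' Electrodes whose absolute voltage reaches at least `ampMinUv` inside
#' the event window; all others are treated as noise electrodes.
#'
#' @param rec an [MEARecording-class].
#' @param event one row of [detectOscillationEvents()] output (or any
#'   list with `onset_s`, `offset_s`).
#' @param ampMinUv amplitude floor in uV (default 30).
#' @return Integer electrode indices.
#' @export
propagatingElectrodes <- function(rec, event, ampMinUv = 30.0) {
  i0 <- max(1L, floor(event$onset_s * rec@fs) + 1L)
  i1 <- min(ncol(rec@voltage), ceiling(event$offset_s * rec@fs) + 1L)
  if (i1 < i0) stop("event window outside recording")
  mx <- apply(abs(rec@voltage[, i0:i1, drop = FALSE]), 1L, max)
  which(mx >= ampMinUv)
}

#' Per-electrode peak times within an event
#'
#' Time from event onset to each electrode's absolute voltage peak
#' (earliest sample on ties).
#'
#' @param rec an [MEARecording-class].
#' @param event event window (`onset_s`, `offset_s`).
#' @param electrodes electrode indices (the propagating set).
#' @return Named numeric vector of peak times (s from onset).
#' @export
peakTimeMap <- function(rec, event, electrodes) {
  i0 <- max(1L, floor(event$onset_s * rec@fs) + 1L)
  i1 <- min(ncol(rec@voltage), ceiling(event$offset_s * rec@fs) + 1L)
  pk <- numeric(length(electrodes))
  for (k in seq_along(electrodes)) {
    seg <- abs(rec@voltage[electrodes[k], i0:i1])
    pk[k] <- (which.max(seg) - 1L) / rec@fs
  }
  names(pk) <- electrodes
  pk
}

#' Electrode recruitment time series
#'
#' Histogram of peak times in bins of `binS`; the counts sum to the
#' number of electrodes.
#'
#' @param peakTimes peak times (s from event onset).
#' @param binS bin width (s, default 0.005).
#' @param durationS histogram span; defaults to the latest peak time.
#' @return List with `counts`, `binS`, `breaks`.
#' @export
recruitmentSeries <- function(peakTimes, binS = 0.005, durationS = NULL) {
  if (binS <= 0) stop("binS must be > 0")
  if (!length(peakTimes)) {
    nb <- if (is.null(durationS)) 1L else max(1L, ceiling(durationS / binS))
    return(list(counts = integer(nb), binS = binS,
                breaks = seq(0, nb * binS, by = binS)))
  }
  if (is.null(durationS)) durationS <- max(peakTimes)
  nb <- max(1L, ceiling(durationS / binS + 1e-9))
  counts <- tabulate(pmin(floor(peakTimes / binS) + 1L, nb), nbins = nb)
  list(counts = counts, binS = binS, breaks = seq(0, nb * binS, by = binS))
}

#' Propagation velocity from the recruitment series
#'
#' Works on the cumulative recruitment curve C(t). The primary estimate
#' is the maximum secant slope of C over sliding windows inside the
#' 10%-90% recruitment range, with window width one quarter of that
#' range (at least one bin) so that lattice-arrival aliasing in single
#' bins does not dominate; the mean slope over the 10%-90% range is
#' reported alongside. When recruitment collapses into a single bin the
#' velocity degenerates to `total / binS` and is flagged.
#'
#' @param recruitment output of [recruitmentSeries()].
#' @param binS bin width (s); defaults to the one in `recruitment`.
#' @return List with `velocity` (electrodes/s, primary), `meanVelocity`,
#'   `degenerate`, `total`.
#' @export
propagationVelocity <- function(recruitment, binS = recruitment$binS) {
  counts <- recruitment$counts
  total <- sum(counts)
  if (total < 1L) stop("recruitment series is empty")
  C <- cumsum(counts)
  i10 <- which(C >= 0.1 * total)[1]
  i90 <- which(C >= 0.9 * total)[1]
  if (i90 <= i10) {
    v <- total / binS
    return(list(velocity = v, meanVelocity = v, degenerate = TRUE,
                total = total))
  }
  span <- i90 - i10
  w <- max(1L, ceiling(span / 4))
  starts <- i10:(i90 - w)
  if (!length(starts)) starts <- i10
  slopes <- (C[pmin(starts + w, i90)] - C[starts]) /
    (pmin(starts + w, i90) - starts) / binS
  meanV <- (C[i90] - C[i10]) / (span * binS)
  list(velocity = max(slopes), meanVelocity = meanV, degenerate = FALSE,
       total = total)
}

#' Propagation area
#'
#' Number of propagating electrodes and the corresponding physical area
#' (`n * electrodeAreaUm2 / 1e6`, mm^2).
#'
#' @param electrodes integer electrode indices.
#' @param grid the [ElectrodeGrid-class].
#' @return List with `nElectrodes`, `areaMm2`.
#' @export
propagationArea <- function(electrodes, grid) {
  n <- length(unique(electrodes))
  list(nElectrodes = n, areaMm2 = n * grid@electrodeAreaUm2 / 1e6)
}

#' Aggregate per-event endpoints to organoid-level means
#'
#' Averages event-level values within each (organoid, condition) cell;
#' these means are the sampling units for the group-comparison layer.
#' Empty cells are absent from the output (missing, not zero).
#'
#' @param df data.frame with one row per event.
#' @param value name of the value column.
#' @param organoid,condition names of the grouping columns.
#' @return data.frame with `organoid`, `condition`, `mean_value`, `n_events`.
#' @export
aggregateEndpoint <- function(df, value, organoid = "organoid_id",
                              condition = "condition") {
  if (!nrow(df))
    return(data.frame(organoid = character(), condition = character(),
                      mean_value = numeric(), n_events = integer()))
  key <- interaction(df[[organoid]], df[[condition]], drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(df)), key), function(ii)
    data.frame(organoid = df[[organoid]][ii[1]],
               condition = df[[condition]][ii[1]],
               mean_value = mean(df[[value]][ii]),
               n_events = length(ii))))
  rownames(agg) <- NULL
  agg[order(agg$organoid, agg$condition), , drop = FALSE]
}
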