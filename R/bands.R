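## Per-electrode frequency-band power maps, standardization, and k-means
## spatial clustering.

#' Default frequency band definitions
#'
#' delta 0.5-3, theta 4-7, alpha 8-11, beta 12-29, gamma 30-100 Hz.
#'
#' @return data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
bandDefinitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo_hz = c(0.5, 4, 8, 12, 30),
             hi_hz = c(3, 7, 11, 29, 100))
}

## Anti-aliased decimation to ~targetFs by an integer factor, zero-phase.
decimateTrace <- function(V, fs, targetFs = 200) {
  fac <- floor(fs / targetFs)
  if (fac <= 1L) return(list(V = V, fs = fs))
  newFs <- fs / fac
  lp <- filterSpec("lowpass", 0.4 * newFs)
  Vf <- zeroPhaseFilter(V, firCoefficients(lp, fs))
  idx <- seq(1L, if (is.null(dim(V))) length(V) else ncol(V), by = fac)
  list(V = if (is.null(dim(Vf))) Vf[idx] else Vf[, idx, drop = FALSE],
       fs = newFs)
}

#' Per-electrode band amplitudes (RMS of band-filtered traces)
#'
#' For each band, each electrode trace within the window is zero-phase
#' FIR bandpass filtered and summarized by its RMS amplitude (uV). Bands
#' with corners below 20 Hz are computed on a trace decimated to about
#' 200 Hz for numerical stability of the long low-frequency filters.
#' Bands whose lower corner has fewer than `minCycles` cycles inside the
#' window are flagged unreliable; a band with less than one full cycle
#' is skipped (all-NA column) with a warning.
#'
#' @param rec a detrended [MEARecording-class].
#' @param window `c(start_s, end_s)` analysis window; default the whole
#'   recording.
#' @param bands band definition data.frame (see [bandDefinitions()]).
#' @param minCycles reliability floor in cycles of the lower corner.
#' @return Numeric matrix electrodes x bands (uV RMS), with attribute
#'   `"unreliable"` naming flagged bands.
#' @export
bandAmplitude <- function(rec, window = NULL, bands = bandDefinitions(),
                          minCycles = 3) {
  fs <- rec@fs
  if (is.null(window)) window <- c(0, recordingDuration(rec))
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(ncol(rec@voltage), ceiling(window[2] * fs))
  if (i1 <= i0) stop("analysis window outside recording")
  V <- rec@voltage[, i0:i1, drop = FALSE]
  winLen <- (i1 - i0 + 1L) / fs
  dec <- NULL
  out <- matrix(NA_real_, nrow(V), nrow(bands),
                dimnames = list(NULL, bands$name))
  unreliable <- character()
  for (b in seq_len(nrow(bands))) {
    lo <- bands$lo_hz[b]; hi <- bands$hi_hz[b]
    cyc <- winLen * lo
    if (cyc < 1) {
      warning("window shorter than one cycle of ", bands$name[b],
              " lower corner; band skipped")
      next
    }
    if (cyc < minCycles) unreliable <- c(unreliable, bands$name[b])
    if (hi < 20 && fs > 400) {
      if (is.null(dec)) dec <- decimateTrace(V, fs)
      src <- dec$V; sfs <- dec$fs
    } else {
      src <- V; sfs <- fs
    }
    spec <- filterSpec("bandpass", c(lo, hi))
    F <- zeroPhaseFilter(src, firCoefficients(spec, sfs))
    out[, b] <- sqrt(rowMeans(F * F))
  }
  attr(out, "unreliable") <- unreliable
  out
}

#' Standardize band power across electrodes
#'
#' Per band, `z = (amp - mean) / SD` over the included electrodes
#' (sample SD). A band with zero SD gets z = 0 and a degenerate flag.
#'
#' @param amp raw amplitude matrix from [bandAmplitude()].
#' @param include electrode indices to standardize over; default all.
#' @return Matrix of z values (rows = included electrodes) with
#'   attributes `"electrodes"` (the included indices) and
#'   `"degenerate"` (bands with zero SD).
#' @export
standardizeBandPower <- function(amp, include = NULL) {
  if (is.null(include)) include <- seq_len(nrow(amp))
  if (length(include) < 2L) stop("need at least 2 electrodes")
  a <- amp[include, , drop = FALSE]
  degenerate <- character()
  z <- a
  for (b in seq_len(ncol(a))) {
    mu <- mean(a[, b]); s <- stats::sd(a[, b])
    if (!is.finite(s) || s == 0) {
      z[, b] <- 0
      degenerate <- c(degenerate, colnames(a)[b])
    } else z[, b] <- (a[, b] - mu) / s
  }
  attr(z, "electrodes") <- include
  attr(z, "degenerate") <- degenerate
  z
}

#' Electrodes with usable signal
#'
#' Pre-filter to electrodes whose broadband RMS reaches a floor
#' (default 1 uV), so dead electrodes do not dominate the z-scaling.
#'
#' @param rec an [MEARecording-class].
#' @param minRmsUv broadband RMS floor (uV).
#' @return Integer electrode indices.
#' @export
usableElectrodes <- function(rec, minRmsUv = 1) {
  rms <- sqrt(rowMeans(rec@voltage^2))
  which(rms >= minRmsUv)
}

#' Spatial k-means clustering of standardized band profiles
#'
#' k-means in 5-band z-space with `nInit` random restarts (best inertia
#' kept), deterministic for a fixed seed. Cluster ids are relabeled by
#' descending cluster size (ties by first occurrence) for stable output.
#'
#' @param z standardized matrix from [standardizeBandPower()].
#' @param k number of clusters (default 9).
#' @param nInit number of restarts.
#' @param maxIter maximum k-means iterations.
#' @param seed integer seed.
#' @return List with `cluster` (id per row of z), `centers` (k x bands),
#'   `sizes`, `totWithinSS`.
#' @export
clusterBands <- function(z, k = 9L, nInit = 20L, maxIter = 300L, seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(z)) stop("k exceeds the number of electrodes")
  set.seed(seedOffset(seed, 42))
  km <- stats::kmeans(z, centers = k, nstart = nInit, iter.max = maxIter)
  ord <- order(-km$size, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(cluster = relabel[km$cluster],
       centers = km$centers[ord, , drop = FALSE],
       sizes = km$size[ord],
       totWithinSS = km$tot.withinss)
}

#' Mean band profile per cluster
#'
#' @param z standardized matrix from [standardizeBandPower()].
#' @param cluster cluster id per row of `z`.
#' @param k number of clusters; default the largest id.
#' @return k x bands matrix of mean standardized intensities (rows of
#'   empty clusters are NA).
#' @export
clusterProfiles <- function(z, cluster, k = max(cluster)) {
  out <- matrix(NA_real_, k, ncol(z),
                dimnames = list(paste0("cluster", seq_len(k)), colnames(z)))
  for (c in seq_len(k)) {
    ii <- which(cluster == c)
    if (length(ii)) out[c, ] <- colMeans(z[ii, , drop = FALSE])
  }
  out
}
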