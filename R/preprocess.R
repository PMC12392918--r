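## Baseline stabilization and zero-phase FIR filtering, applied before
## all downstream stages.

#' Segment-wise least-squares detrending with offset correction
#'
#' Partitions the trace into consecutive segments of `segmentLen`
#' samples, removes the best least-squares line from each segment, then
#' subtracts the segment mean. The final partial segment is processed
#' the same way (offset-corrected only if it has a single sample). The
#' operation is idempotent.
#'
#' @param x numeric voltage vector (uV).
#' @param segmentLen segment length in samples (>= 2).
#' @return Detrended vector of the same length.
#' @export
detrendOffset <- function(x, segmentLen = 500L) {
  segmentLen <- as.integer(segmentLen)
  if (is.na(segmentLen) || segmentLen < 2L)
    stop("segmentLen must be an integer >= 2")
  if (!all(is.finite(x))) stop("trace contains non-finite values")
  n <- length(x)
  if (n == 0L) return(x)
  out <- x
  starts <- seq.int(1L, n, by = segmentLen)
  for (s in starts) {
    e <- min(s + segmentLen - 1L, n)
    seg <- x[s:e]
    m <- length(seg)
    if (m >= 2L) {
      t <- seq_len(m) - (m + 1) / 2          # centered time axis
      b <- sum(t * seg) / sum(t * t)         # LS slope
      res <- seg - mean(seg) - b * t         # line removed
      out[s:e] <- res - mean(res)            # offset correction
    } else {
      out[s:e] <- 0
    }
  }
  out
}

#' Detrend every electrode of a recording
#'
#' Applies [detrendOffset()] to each electrode trace.
#'
#' @param rec an [MEARecording-class].
#' @param segmentLen segment length in samples.
#' @return A detrended [MEARecording-class].
#' @export
preprocessRecording <- function(rec, segmentLen = 500L) {
  v <- rec@voltage
  for (e in seq_len(nrow(v))) v[e, ] <- detrendOffset(v[e, ], segmentLen)
  initialize(rec, voltage = v)
}

#' FIR filter specification
#'
#' Describes a zero-phase FIR filter. The passband corners are taken as
#' given; the transition bandwidth defaults to 20% of the lower corner
#' (minimum 0.5 Hz) and sets the tap count by the Hamming-window rule
#' `taps ~ 3.3 * fs / transition` (made odd, capped at 8191).
#'
#' @param kind one of "highpass", "bandpass", "lowpass".
#' @param cutoffsHz one corner (high/lowpass) or two corners (bandpass),
#'   in Hz.
#' @param taps optional odd tap count; computed from the transition
#'   bandwidth when NULL.
#' @param zeroPhase must be TRUE (the only supported mode).
#' @return A `filterSpec` list.
#' @export
filterSpec <- function(kind = c("highpass", "bandpass", "lowpass"),
                       cutoffsHz, taps = NULL, zeroPhase = TRUE) {
  kind <- match.arg(kind)
  nc <- if (kind == "bandpass") 2L else 1L
  if (length(cutoffsHz) != nc)
    stop(kind, " needs ", nc, " cutoff frequency/frequencies")
  if (any(!is.finite(cutoffsHz)) || any(cutoffsHz <= 0))
    stop("cutoffs must be positive and finite")
  if (nc == 2L && cutoffsHz[1] >= cutoffsHz[2])
    stop("bandpass cutoffs must be increasing")
  if (!isTRUE(zeroPhase)) stop("only zero-phase filtering is supported")
  structure(list(kind = kind, cutoffsHz = as.numeric(cutoffsHz),
                 taps = taps, zeroPhase = TRUE),
            class = "filterSpec")
}

## FIR coefficients for a spec at sampling rate fs.
firCoefficients <- function(spec, fs) {
  co <- spec$cutoffsHz
  if (any(co >= fs / 2))
    stop("filter cutoff at or above Nyquist (fs/2 = ", fs / 2, " Hz)")
  taps <- spec$taps
  if (is.null(taps)) {
    tw <- max(0.2 * min(co), 0.5)
    taps <- ceiling(3.3 * fs / tw)
  }
  taps <- as.integer(taps)
  if (taps %% 2L == 0L) taps <- taps + 1L
  taps <- max(11L, min(taps, 8191L))
  type <- switch(spec$kind, highpass = "high", bandpass = "pass",
                 lowpass = "low")
  as.numeric(signal::fir1(taps - 1L, co / (fs / 2), type = type))
}

## Zero-phase filtering core. Equivalent to a forward-backward pass of
## the FIR filter b (overall response |B(w)|^2, zero phase), computed by
## FFT convolution with the autocorrelation of b, after reflect-padding
## the trace by one filter length to suppress edge transients.
## Accepts a vector or an electrodes-x-samples matrix (filtered by row).
zeroPhaseFilter <- function(x, b) {
  vec <- is.null(dim(x))
  V <- if (vec) matrix(x, nrow = 1L) else x
  n <- ncol(V)
  np <- length(b)
  if (n < 2L) return(x)
  pad <- min(np, n - 1L)
  g <- convFFT(b, rev(b))                  # length 2*np - 1, symmetric
  m <- n + 2L * pad
  N <- stats::nextn(m + length(g) - 1L, 2)
  G <- stats::fft(c(g, numeric(N - length(g))))
  out <- V
  li <- (pad + 1L):2L                      # left reflection indices
  ri <- (n - 1L):(n - pad)                 # right reflection indices
  for (e in seq_len(nrow(V))) {
    xr <- V[e, ]
    xp <- c(xr[li], xr, xr[ri])
    y <- Re(stats::fft(stats::fft(c(xp, numeric(N - m))) * G,
                       inverse = TRUE)) / N
    out[e, ] <- y[(np + pad):(np + pad + n - 1L)]
  }
  if (vec) out[1L, ] else out
}

## Linear FFT convolution.
convFFT <- function(a, b) {
  n <- length(a) + length(b) - 1L
  N <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(a, numeric(N - length(a)))) *
                     stats::fft(c(b, numeric(N - length(b)))),
                     inverse = TRUE)) / N
  y[seq_len(n)]
}

#' Apply a zero-phase FIR filter
#'
#' Filters a trace (or every row of an electrodes x samples matrix) with
#' the zero-phase realization of the FIR filter described by `spec`
#' (forward-backward equivalent, so an in-band sinusoid passes with no
#' phase shift). Edges are reflect-padded by one filter length.
#'
#' @param x numeric vector, or matrix filtered row-wise.
#' @param spec a [filterSpec()].
#' @param fs sampling rate in Hz.
#' @return Filtered data with the same shape as `x`.
#' @export
applyFilter <- function(x, spec, fs) {
  if (!inherits(spec, "filterSpec")) stop("spec must be a filterSpec")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  zeroPhaseFilter(x, firCoefficients(spec, fs))
}

#' High-pass filter a recording for spike detection
#'
#' Applies the standard zero-phase FIR high-pass (default 100 Hz) to
#' every electrode trace.
#'
#' @param rec an [MEARecording-class].
#' @param cutoffHz high-pass corner in Hz.
#' @param taps optional tap count override.
#' @return A filtered [MEARecording-class].
#' @export
highpassRecording <- function(rec, cutoffHz = 100, taps = NULL) {
  spec <- filterSpec("highpass", cutoffHz, taps = taps)
  initialize(rec, voltage = zeroPhaseFilter(rec@voltage,
                                            firCoefficients(spec, rec@fs)))
}
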