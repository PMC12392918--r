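#' @import methods
NULL

#' Electrode grid geometry
#'
#' Describes the rectangular electrode lattice of a dense CMOS MEA:
#' number of rows and columns, center-to-center pitch and per-electrode
#' sensing area. The default geometry reproduces a 236,880-electrode
#' array (420 x 564) with 10.52 um pitch and 110.67 um^2 electrodes;
#' analyses at desk scale use much smaller grids.
#'
#' Electrode indices are 1-based and row-major: electrode `e` sits at
#' `row = (e - 1) %/% nCols + 1`, `col = (e - 1) %% nCols + 1`, and its
#' center position in um is `((col - 1) * pitchUm, (row - 1) * pitchUm)`
#' with the origin at electrode 1. This mapping is the single source of
#' truth used by every analysis stage.
#'
#' @slot nRows integer, number of electrode rows (>= 1).
#' @slot nCols integer, number of electrode columns (>= 1).
#' @slot pitchUm numeric, center-to-center electrode pitch in um (> 0).
#' @slot electrodeAreaUm2 numeric, sensing area of one electrode in um^2.
#'
#' @examples
#' g <- ElectrodeGrid(nRows = 4, nCols = 4)
#' nElectrodes(g)
#' electrodePositions(g)
#' @export
setClass("ElectrodeGrid",
  representation(
    nRows = "integer",
    nCols = "integer",
    pitchUm = "numeric",
    electrodeAreaUm2 = "numeric"
  )
)

setValidity("ElectrodeGrid", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single integer >= 1")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single integer >= 1")
  if (length(object@pitchUm) != 1L || !is.finite(object@pitchUm) ||
      object@pitchUm <= 0)
    msg <- c(msg, "pitchUm must be a single positive number")
  if (length(object@electrodeAreaUm2) != 1L ||
      !is.finite(object@electrodeAreaUm2) || object@electrodeAreaUm2 <= 0)
    msg <- c(msg, "electrodeAreaUm2 must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an electrode grid
#'
#' @param nRows,nCols grid dimensions (defaults give the full
#'   236,880-electrode array).
#' @param pitchUm center-to-center pitch in um.
#' @param electrodeAreaUm2 per-electrode sensing area in um^2.
#' @return An [ElectrodeGrid-class] object.
#' @export
ElectrodeGrid <- function(nRows = 420L, nCols = 564L, pitchUm = 10.52,
                          electrodeAreaUm2 = 110.67) {
  new("ElectrodeGrid", nRows = as.integer(nRows), nCols = as.integer(nCols),
      pitchUm = as.numeric(pitchUm),
      electrodeAreaUm2 = as.numeric(electrodeAreaUm2))
}

setMethod("show", "ElectrodeGrid", function(object) {
  cat(sprintf("ElectrodeGrid: %d x %d (%d electrodes), pitch %.2f um, area %.2f um^2\n",
              object@nRows, object@nCols, object@nRows * object@nCols,
              object@pitchUm, object@electrodeAreaUm2))
})

#' MEA voltage recording
#'
#' Container for a dense-grid extracellular voltage recording: a voltage
#' matrix (electrodes x samples, uV), the sampling rate, the electrode
#' grid geometry and optional per-electrode region labels (used for
#' assembloids, e.g. "striatum" / "midbrain").
#'
#' @slot voltage numeric matrix, electrodes x samples, in uV.
#' @slot fs numeric, sampling rate in Hz.
#' @slot grid [ElectrodeGrid-class] geometry; `nrow(voltage)` must equal
#'   `nRows * nCols`.
#' @slot regionLabels character, length 0 (absent) or one label per
#'   electrode.
#' @slot t0 numeric, start time in seconds.
#' @export
setClass("MEARecording",
  representation(
    voltage = "matrix",
    fs = "numeric",
    grid = "ElectrodeGrid",
    regionLabels = "character",
    t0 = "numeric"
  )
)

setValidity("MEARecording", function(object) {
  msg <- character()
  ne <- object@grid@nRows * object@grid@nCols
  if (!is.numeric(object@voltage))
    msg <- c(msg, "voltage must be a numeric matrix")
  if (nrow(object@voltage) != ne)
    msg <- c(msg, sprintf(
      "voltage has %d rows but grid defines %d electrodes",
      nrow(object@voltage), ne))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!(length(object@regionLabels) %in% c(0L, nrow(object@voltage))))
    msg <- c(msg, "regionLabels must be empty or one label per electrode")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (is.numeric(object@voltage) && anyNA(object@voltage))
    msg <- c(msg, "voltage contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct an MEA recording
#'
#' @param voltage numeric matrix, electrodes x samples (uV).
#' @param fs sampling rate in Hz.
#' @param grid an [ElectrodeGrid-class]; its electrode count must match
#'   `nrow(voltage)`.
#' @param regionLabels optional character vector, one label per electrode.
#' @param t0 start time in seconds.
#' @return An [MEARecording-class] object.
#' @export
MEARecording <- function(voltage, fs, grid, regionLabels = NULL, t0 = 0) {
  if (is.null(regionLabels)) regionLabels <- character()
  new("MEARecording", voltage = voltage, fs = as.numeric(fs), grid = grid,
      regionLabels = as.character(regionLabels), t0 = as.numeric(t0))
}

setMethod("show", "MEARecording", function(object) {
  cat(sprintf("MEARecording: %d electrodes x %d samples @ %g Hz (%.3f s)\n",
              nrow(object@voltage), ncol(object@voltage), object@fs,
              ncol(object@voltage) / object@fs))
  show(object@grid)
  if (length(object@regionLabels))
    cat("regions:", paste(unique(object@regionLabels), collapse = ", "), "\n")
})

#' Ground truth of a synthetic recording
#'
#' Everything the synthetic generator planted: neuron specifications with
#' their exact spike times, wave specifications, band-field
#' specifications, couplings with triggered-spike parentage, network
#' burst windows and the noise model. Used as the recovery oracle for
#' every analysis stage.
#'
#' @slot neurons list of neuron specs (see [neuronSpec()]).
#' @slot spikes data.frame with columns `neuron`, `time_s`, `triggered`.
#' @slot waves list of wave specs (see [waveSpec()]).
#' @slot bandFields band field spec or NULL (see [bandFieldSpec()]).
#' @slot couplings list of coupling specs (see [couplingSpec()]).
#' @slot parentage data.frame with columns `coupling`, `pre`, `post`,
#'   `pre_time_s`, `post_time_s` for triggered spikes.
#' @slot burstWindows data.frame with columns `start_s`, `end_s`.
#' @slot noiseSigmaUv numeric, per-sample Gaussian noise SD in uV.
#' @export
setClass("GroundTruth",
  representation(
    neurons = "list",
    spikes = "data.frame",
    waves = "list",
    bandFields = "ANY",
    couplings = "list",
    parentage = "data.frame",
    burstWindows = "data.frame",
    noiseSigmaUv = "numeric"
  )
)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d neurons, %d spikes (%d triggered), %d waves, %d couplings\n",
              length(object@neurons), nrow(object@spikes),
              sum(object@spikes$triggered), length(object@waves),
              length(object@couplings)))
})

#' Identified somas
#'
#' Result of [identifySomas()]: one row per soma in `somaTable()`, with
#' member electrode sets and deduplicated spike trains accessible via
#' [somaMembers()] and [somaTrains()].
#'
#' @slot table data.frame with columns `soma_id`, `x_um`, `y_um`,
#'   `n_spikes`, `n_electrodes`, `member_electrodes` (";"-joined).
#' @slot trains list of numeric spike-time vectors (seconds), one per soma.
#' @slot members list of integer electrode-index vectors, one per soma.
#' @slot grid the [ElectrodeGrid-class] the electrodes live on.
#' @export
setClass("SomaSet",
  representation(
    table = "data.frame",
    trains = "list",
    members = "list",
    grid = "ElectrodeGrid"
  )
)

setValidity("SomaSet", function(object) {
  n <- nrow(object@table)
  if (length(object@trains) != n || length(object@members) != n)
    return("trains/members length must match the soma table")
  TRUE
})

setMethod("show", "SomaSet", function(object) {
  cat(sprintf("SomaSet: %d somas, %d spikes total\n",
              nrow(object@table), sum(object@table$n_spikes)))
})

setMethod("length", "SomaSet", function(x) nrow(x@table))
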