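#' Number of electrodes on a grid
#'
#' @param grid an [ElectrodeGrid-class].
#' @return Integer electrode count (`nRows * nCols`).
#' @export
nElectrodes <- function(grid) grid@nRows * grid@nCols

#' Electrode index to (row, col)
#'
#' Electrode indices are 1-based and row-major (see
#' [ElectrodeGrid-class]).
#'
#' @param grid an [ElectrodeGrid-class].
#' @param e integer electrode indices.
#' @return Integer matrix with columns `row`, `col`.
#' @export
electrodeRowCol <- function(grid, e) {
  e <- as.integer(e)
  if (any(e < 1L | e > nElectrodes(grid)))
    stop("electrode index out of range")
  cbind(row = (e - 1L) %/% grid@nCols + 1L,
        col = (e - 1L) %% grid@nCols + 1L)
}

#' (row, col) to electrode index
#'
#' @param grid an [ElectrodeGrid-class].
#' @param row,col 1-based row and column indices.
#' @return Integer electrode indices.
#' @export
electrodeIndex <- function(grid, row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 1L | row > grid@nRows | col < 1L | col > grid@nCols))
    stop("row/col out of range")
  (row - 1L) * grid@nCols + col
}

#' Electrode center positions in um
#'
#' @param grid an [ElectrodeGrid-class].
#' @param e electrode indices; default all electrodes.
#' @return Numeric matrix with columns `x_um`, `y_um`; origin at
#'   electrode 1, x along columns, y along rows.
#' @export
electrodePositions <- function(grid, e = seq_len(nElectrodes(grid))) {
  rc <- electrodeRowCol(grid, e)
  cbind(x_um = (rc[, "col"] - 1) * grid@pitchUm,
        y_um = (rc[, "row"] - 1) * grid@pitchUm)
}

#' Euclidean distance between electrode centers
#'
#' @param grid an [ElectrodeGrid-class].
#' @param a,b electrode indices (recycled to common length).
#' @return Numeric distances in um.
#' @export
electrodeDistanceUm <- function(grid, a, b) {
  pa <- electrodePositions(grid, a)
  pb <- electrodePositions(grid, b)
  sqrt((pa[, 1] - pb[, 1])^2 + (pa[, 2] - pb[, 2])^2)
}

#' Accessors for MEARecording
#'
#' `voltageMatrix()` returns the electrodes x samples voltage matrix
#' (uV); `samplingRate()` the sampling rate (Hz); `electrodeGrid()` the
#' grid geometry; `regionLabels()` the per-electrode region labels (or
#' NULL); `recordingDuration()` the duration in seconds;
#' `recordingTimes()` the per-sample time axis in seconds.
#'
#' @param rec an [MEARecording-class].
#' @return See description.
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
voltageMatrix <- function(rec) rec@voltage

#' @rdname recording-accessors
#' @export
samplingRate <- function(rec) rec@fs

#' @rdname recording-accessors
#' @export
electrodeGrid <- function(rec) rec@grid

#' @rdname recording-accessors
#' @export
regionLabels <- function(rec) {
  if (length(rec@regionLabels)) rec@regionLabels else NULL
}

#' @rdname recording-accessors
#' @export
recordingDuration <- function(rec) ncol(rec@voltage) / rec@fs

#' @rdname recording-accessors
#' @export
recordingTimes <- function(rec) {
  rec@t0 + (seq_len(ncol(rec@voltage)) - 1L) / rec@fs
}

#' Accessors for SomaSet
#'
#' `somaTable()` returns the per-soma summary data.frame; `somaTrains()`
#' the list of deduplicated spike-time vectors (seconds);
#' `somaMembers()` the list of member electrode index vectors;
#' `somaPositions()` the spike-count-weighted centroid positions (um).
#'
#' @param x a [SomaSet-class].
#' @return See description.
#' @name soma-accessors
NULL

#' @rdname soma-accessors
#' @export
somaTable <- function(x) x@table

#' @rdname soma-accessors
#' @export
somaTrains <- function(x) x@trains

#' @rdname soma-accessors
#' @export
somaMembers <- function(x) x@members

#' @rdname soma-accessors
#' @export
somaPositions <- function(x) {
  cbind(x_um = x@table$x_um, y_um = x@table$y_um)
}
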