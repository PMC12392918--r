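## Recording container: a small self-describing binary file.
## Layout: 8-byte magic "FPIMEA01", int32 header length, UTF-8 JSON
## header (fs, grid, t0, n_samples, region labels), then the voltage
## matrix as little-endian float32, column-major (R native order,
## electrodes x samples). Deterministic: identical recordings produce
## identical bytes.

.FPI_MAGIC <- charToRaw("FPIMEA01")

#' Write a recording to a container file
#'
#' Stores the voltage matrix as little-endian 32-bit floats together
#' with all metadata (sampling rate, grid geometry, region labels, start
#' time) in a JSON header. The format round-trips through
#' [readRecording()] exactly at float32 precision and two writes of the
#' same recording are byte-identical.
#'
#' @param rec an [MEARecording-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "MEARecording"))
  validObject(rec)
  g <- rec@grid
  header <- list(
    format = "FPIMEA", version = 1L,
    fs = rec@fs, t0 = rec@t0,
    n_rows = g@nRows, n_cols = g@nCols,
    pitch_um = g@pitchUm, electrode_area_um2 = g@electrodeAreaUm2,
    n_samples = ncol(rec@voltage)
  )
  if (length(rec@regionLabels)) header$region_labels <- rec@regionLabels
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(hjson))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.FPI_MAGIC, con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(rec@voltage), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a recording from a container file
#'
#' @param path path to a file written by [writeRecording()].
#' @return An [MEARecording-class].
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, .FPI_MAGIC))
    stop("not an FPIMEA recording container: ", path)
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  for (f in c("fs", "n_rows", "n_cols", "pitch_um", "electrode_area_um2",
              "n_samples"))
    if (is.null(header[[f]]))
      stop("recording container is missing metadata field '", f, "'")
  ne <- as.integer(header$n_rows) * as.integer(header$n_cols)
  ns <- as.integer(header$n_samples)
  v <- readBin(con, "numeric", n = ne * ns, size = 4L, endian = "little")
  if (length(v) != ne * ns)
    stop(sprintf(
      "voltage payload has %d values but metadata implies %d x %d",
      length(v), ne, ns))
  grid <- ElectrodeGrid(header$n_rows, header$n_cols, header$pitch_um,
                        header$electrode_area_um2)
  MEARecording(matrix(v, nrow = ne, ncol = ns), fs = header$fs, grid = grid,
               regionLabels = header$region_labels,
               t0 = if (is.null(header$t0)) 0 else header$t0)
}

#' Write a result table as CSV
#'
#' Writes a data.frame as RFC-4180 CSV (header row, UTF-8, "." decimal
#' separator). List columns are not allowed; collapse them first (the
#' soma table does this for member electrodes).
#'
#' @param tbl a data.frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeResultTable <- function(tbl, path) {
  if (!is.data.frame(tbl)) stop("tbl must be a data.frame")
  if (any(vapply(tbl, is.list, logical(1))))
    stop("list columns are not allowed in a result table")
  utils::write.csv(tbl, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
readResultTable <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}
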