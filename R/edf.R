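## Minimal EDF (16-bit European Data Format) I/O. Supports continuous
## recordings with a common integer sampling rate across channels, which
## covers the package's export/import needs; richer EDF+ annotations are
## out of scope.

.padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one-second data records; the sampling rate must be a
#' positive integer. Physical calibration is per channel, spanning the
#' channel's observed range.
#'
#' @param rec an \code{\link{IEEGRecording}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  fs <- rec@fs
  stopifnot(fs == round(fs), fs > 0)
  X <- rec@data
  ns <- nrow(X)
  nRec <- floor(ncol(X) / fs)
  stopifnot(nRec >= 1)
  X <- X[, seq_len(nRec * fs), drop = FALSE]
  physMin <- apply(X, 1, min); physMax <- apply(X, 1, max)
  same <- physMax - physMin < 1e-12
  physMax[same] <- physMin[same] + 1
  digMin <- -32768; digMax <- 32767
  D <- round((X - physMin) / (physMax - physMin) * (digMax - digMin) + digMin)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.padField(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr(format(rec@epochStart, "%d.%m.%y"), 8)
  wr(format(rec@epochStart, "%H.%M.%S"), 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(nRec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in rec@channels$label) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in physMin) wr(formatC(v, digits = 5, format = "g"), 8)
  for (v in physMax) wr(formatC(v, digits = 5, format = "g"), 8)
  for (i in seq_len(ns)) wr(digMin, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(D[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' @param path EDF file path.
#' @param tissue optional tissue vector for the channel metadata.
#' @return an \code{\link{IEEGRecording}} with \code{scheme = "machine"}.
#' @export
readEDF <- function(path, tissue = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                 # version
  rd(80); rd(80)                        # patient / recording id
  date <- rd(8); time <- rd(8)
  rd(8); rd(44)
  nRec <- as.integer(rd(8))
  durS <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)         # transducer
  for (i in seq_len(ns)) rd(8)          # physical dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)         # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / durS
  X <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    X[, cols] <- matrix(raw, ns, spr[1], byrow = TRUE)
  }
  scale <- (physMax - physMin) / (digMax - digMin)
  X <- X * scale + (physMin - digMin * scale)
  start <- as.POSIXct(paste(date, time), format = "%d.%m.%y %H.%M.%S",
                      tz = "UTC")
  if (is.na(start))
    start <- as.POSIXct("2000-01-01 13:00:00", tz = "UTC")
  ieegRecording(X, fs = fs, channels = makeChannelInfo(labels,
                                                       tissue = tissue),
                epochStart = start)
}
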