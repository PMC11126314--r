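#' Construct an IEEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channels either a character vector of channel labels (metadata is
#'   derived with \code{\link{makeChannelInfo}}) or a full channel metadata
#'   \code{data.frame}.
#' @param scheme reference scheme tag; recordings are ingested as
#'   \code{"machine"}.
#' @param epochStart POSIXct start time.
#' @return an \code{\link{IEEGRecording}}.
#' @examples
#' rec <- ieegRecording(matrix(rnorm(200), 2), fs = 100,
#'                      channels = c("LA01", "LA02"))
#' nChannels(rec)
#' @export
ieegRecording <- function(data, fs, channels, scheme = "machine",
                          epochStart = as.POSIXct("2000-01-01 13:00:00",
                                                  tz = "UTC")) {
  data <- as.matrix(data)
  if (is.character(channels)) channels <- makeChannelInfo(channels)
  rownames(data) <- channels$label
  new("IEEGRecording", data = data, fs = as.numeric(fs), channels = channels,
      scheme = scheme, epochStart = epochStart)
}

#' Construct an EpochSet
#' @param epochs list of \code{IEEGRecording} objects with shared channels.
#' @param epochLength epoch duration (s); defaults to the duration of the
#'   first epoch.
#' @return an \code{\link{EpochSet}}.
#' @export
epochSet <- function(epochs, epochLength = NULL) {
  if (is.null(epochLength))
    epochLength <- ncol(epochs[[1]]@data) / epochs[[1]]@fs
  new("EpochSet", epochs = epochs, epochLength = epochLength)
}

#' Construct a ConnectivityNetwork
#' @param weights symmetric matrix (diagonal set to NA).
#' @param nodes node names.
#' @param measure measure id.
#' @param band band name or NA.
#' @param scheme reference scheme.
#' @param nWindows windows used in the estimate.
#' @param anchors per-node anchor contact label (defaults to \code{nodes}).
#' @return a \code{\link{ConnectivityNetwork}}.
#' @export
connectivityNetwork <- function(weights, nodes, measure, band = NA_character_,
                                scheme = "machine", nWindows = 0,
                                anchors = nodes) {
  weights <- as.matrix(weights)
  diag(weights) <- NA_real_
  dimnames(weights) <- list(nodes, nodes)
  new("ConnectivityNetwork", weights = weights, nodes = nodes,
      anchors = anchors, measure = measure, band = as.character(band),
      scheme = scheme, nWindows = as.numeric(nWindows))
}

#' @rdname IEEGRecording-class
#' @export
setMethod("signalData", "IEEGRecording", function(x) x@data)
#' @rdname IEEGRecording-class
#' @export
setMethod("samplingRate", "IEEGRecording", function(x) x@fs)
#' @rdname IEEGRecording-class
#' @export
setMethod("channelInfo", "IEEGRecording", function(x) x@channels)
#' @rdname IEEGRecording-class
#' @export
setMethod("referenceScheme", "IEEGRecording", function(x) x@scheme)
#' @rdname IEEGRecording-class
#' @export
setMethod("nChannels", "IEEGRecording", function(x) nrow(x@data))

#' @rdname EpochSet-class
#' @param x an \code{EpochSet}
#' @export
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @rdname EpochSet-class
#' @export
setMethod("nChannels", "EpochSet", function(x) nrow(x@epochs[[1]]@data))
#' @rdname EpochSet-class
#' @export
setMethod("channelInfo", "EpochSet", function(x) x@epochs[[1]]@channels)
#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@epochs[[1]]@fs)
#' @rdname EpochSet-class
#' @export
setMethod("length", "EpochSet", function(x) length(x@epochs))

#' @rdname ConnectivityNetwork-class
#' @param x a \code{ConnectivityNetwork}
#' @export
setMethod("edgeWeights", "ConnectivityNetwork", function(x) x@weights)
#' @rdname ConnectivityNetwork-class
#' @export
setMethod("networkNodes", "ConnectivityNetwork", function(x) x@nodes)
#' @rdname ConnectivityNetwork-class
#' @export
setMethod("nodeAnchors", "ConnectivityNetwork", function(x) x@anchors)
#' @rdname ConnectivityNetwork-class
#' @export
setMethod("referenceScheme", "ConnectivityNetwork", function(x) x@scheme)

setMethod("show", "IEEGRecording", function(object) {
  cat(sprintf("IEEGRecording: %d channels x %d samples @ %g Hz [%s]\n",
              nrow(object@data), ncol(object@data), object@fs, object@scheme))
  cat(sprintf("  retained: %d / %d channels; duration %.1f s\n",
              sum(object@channels$retained), nrow(object@channels),
              ncol(object@data) / object@fs))
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs of %g s, %d channels @ %g Hz\n",
              length(object@epochs), object@epochLength,
              nrow(object@epochs[[1]]@data), object@epochs[[1]]@fs))
})

setMethod("show", "ConnectivityNetwork", function(object) {
  bd <- if (is.na(object@band)) "" else paste0("-", object@band)
  cat(sprintf("ConnectivityNetwork: %s-%s%s, %d nodes, %g windows\n",
              object@scheme, object@measure, bd, length(object@nodes),
              object@nWindows))
  v <- object@weights[upper.tri(object@weights)]
  if (length(v))
    cat(sprintf("  edge weights: median %.3g [%.3g, %.3g]\n",
                stats::median(v, na.rm = TRUE), min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
})
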