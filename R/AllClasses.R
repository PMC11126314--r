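#' @import methods
NULL

setOldClass("POSIXct")

#' IEEGRecording: a multichannel intracranial EEG recording
#'
#' Container for a channels-by-samples voltage matrix (microvolts) together
#' with its sampling rate, per-channel metadata, and the reference scheme the
#' signals are currently expressed in. Recordings enter the package with
#' \code{scheme = "machine"} (the original distant recording reference) and
#' are transformed to \code{"car"} or \code{"bipolar"} by
#' \code{\link{applyReference}}.
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channels \code{data.frame} of channel metadata with columns
#'   \code{label}, \code{electrode}, \code{contact}, \code{hemisphere}
#'   (\code{"L"}, \code{"R"} or \code{"unknown"}), \code{tissue}
#'   (\code{"grey"}, \code{"white"}, \code{"csf"} or \code{"unknown"}) and
#'   logical \code{retained}.
#' @slot scheme reference scheme: \code{"machine"}, \code{"car"} or
#'   \code{"bipolar"}.
#' @slot epochStart POSIXct start time of the recording/epoch.
#'
#' @seealso \code{\link{ieegRecording}}, \code{\link{applyReference}}
#' @export
setClass("IEEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channels = "data.frame",
    scheme = "character",
    epochStart = "POSIXct"
  )
)

.validIEEGRecording <- function(object) {
  msg <- character(0)
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  req <- c("label", "electrode", "contact", "hemisphere", "tissue", "retained")
  if (!all(req %in% names(object@channels)))
    msg <- c(msg, paste("channels must have columns:", paste(req, collapse = ", ")))
  if (nrow(object@data) != nrow(object@channels))
    msg <- c(msg, "row count of data must equal number of channel metadata rows")
  if (!object@scheme %in% c("machine", "car", "bipolar"))
    msg <- c(msg, "scheme must be one of machine, car, bipolar")
  if ("retained" %in% names(object@channels)) {
    keep <- which(object@channels$retained)
    if (length(keep) && !all(is.finite(object@data[keep, , drop = FALSE])))
      msg <- c(msg, "retained channels must contain only finite values")
  }
  if (length(msg)) msg else TRUE
}
setValidity("IEEGRecording", .validIEEGRecording)

#' EpochSet: a set of equal-length epochs from one patient
#'
#' Holds several epochs (each an \code{\link{IEEGRecording}}) sharing the
#' same channel ordering and sampling rate. The canonical study design uses
#' five 2-minute interictal epochs per patient.
#'
#' @slot epochs list of \code{IEEGRecording} objects.
#' @slot epochLength epoch duration in seconds.
#' @export
setClass("EpochSet",
  representation(epochs = "list", epochLength = "numeric")
)

setValidity("EpochSet", function(object) {
  msg <- character(0)
  if (!length(object@epochs)) msg <- c(msg, "at least one epoch required")
  if (!all(vapply(object@epochs, is, logical(1), "IEEGRecording")))
    msg <- c(msg, "all epochs must be IEEGRecording objects")
  if (!length(msg)) {
    labs <- lapply(object@epochs, function(e) e@channels$label)
    if (length(unique(vapply(labs, paste, "", collapse = "\r"))) != 1L)
      msg <- c(msg, "all epochs must share the same channel ordering")
    fss <- vapply(object@epochs, function(e) e@fs, 0)
    if (length(unique(fss)) != 1L)
      msg <- c(msg, "all epochs must share the same sampling rate")
    ns <- vapply(object@epochs, function(e) ncol(e@data), 0L)
    if (any(abs(ns - object@epochLength * fss[1]) > 0.5))
      msg <- c(msg, "each epoch must have duration epochLength")
  }
  if (length(msg)) msg else TRUE
})

#' ConnectivityNetwork: a symmetric functional-connectivity network
#'
#' An undirected node-by-node edge-weight matrix produced by one
#' pre-processing pipeline. Nodes are derived-channel names (contact labels
#' for machine/CAR montages, \code{"LA01-LA02"}-style names for bipolar
#' montages); each node carries an anchor contact label used to align
#' networks across montages. The diagonal is undefined and stored as
#' \code{NA}.
#'
#' @slot weights symmetric numeric matrix; diagonal \code{NA}.
#' @slot nodes character vector of node names.
#' @slot anchors character vector, per-node anchor contact label.
#' @slot measure measure id: one of \code{"pearson"}, \code{"pearson_sq"},
#'   \code{"xcorr"}, \code{"coh"}, \code{"plv"}, \code{"re"}.
#' @slot band frequency-band name for spectral measures, \code{NA} otherwise.
#' @slot scheme reference scheme the network was computed under.
#' @slot nWindows number of 2-s windows that entered the estimate.
#' @export
setClass("ConnectivityNetwork",
  representation(
    weights = "matrix",
    nodes = "character",
    anchors = "character",
    measure = "character",
    band = "character",
    scheme = "character",
    nWindows = "numeric"
  )
)

setValidity("ConnectivityNetwork", function(object) {
  msg <- character(0)
  W <- object@weights
  n <- length(object@nodes)
  if (nrow(W) != n || ncol(W) != n)
    msg <- c(msg, "weights must be a square matrix matching nodes")
  if (length(object@anchors) != n)
    msg <- c(msg, "anchors must match nodes in length")
  off <- W; diag(off) <- 0
  if (any(is.finite(off) != is.finite(t(off))) ||
      max(abs(off - t(off)), na.rm = TRUE) > 0)
    msg <- c(msg, "weights must be symmetric")
  if (!object@measure %in% c("pearson", "pearson_sq", "xcorr", "coh", "plv", "re"))
    msg <- c(msg, "unknown measure id")
  v <- off[upper.tri(off)]
  v <- v[is.finite(v)]
  if (length(v)) {
    tol <- 1e-8
    rng <- switch(object@measure,
      pearson = c(-1, 1),
      pearson_sq = c(0, 1), xcorr = c(0, 1), coh = c(0, 1), plv = c(0, 1),
      re = c(0, Inf))
    if (min(v) < rng[1] - tol || max(v) > rng[2] + tol)
      msg <- c(msg, sprintf("edge weights outside admissible range for %s",
                            object@measure))
  }
  if (length(msg)) msg else TRUE
})
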