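#' @rdname IEEGRecording-class
#' @param object,x an object
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname IEEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname IEEGRecording-class
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' @rdname IEEGRecording-class
#' @export
setGeneric("referenceScheme", function(x) standardGeneric("referenceScheme"))

#' @rdname IEEGRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname ConnectivityNetwork-class
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname ConnectivityNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname ConnectivityNetwork-class
#' @export
setGeneric("nodeAnchors", function(x) standardGeneric("nodeAnchors"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
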