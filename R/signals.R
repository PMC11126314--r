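#' Parse iEEG channel labels into electrode and contact number
#'
#' Clinical iEEG labels concatenate an alphabetic electrode name and a
#' contact number, e.g. \code{"LA01"} is contact 1 of depth electrode LA.
#' The electrode prefix is the maximal leading non-numeric part of the
#' label (separators \code{"-"} and whitespace stripped, case preserved);
#' the contact index is the trailing integer. Zero padding is optional:
#' \code{"LA1"} and \code{"LA01"} parse identically.
#'
#' @param labels character vector of channel labels.
#' @return \code{data.frame} with columns \code{label}, \code{electrode},
#'   \code{contact}.
#' @examples
#' parseChannelLabel(c("LA01", "RGRID12"))
#' @export
parseChannelLabel <- function(labels) {
  stopifnot(is.character(labels), length(labels) > 0, !is.na(labels),
            nzchar(labels))
  clean <- gsub("[-[:space:]]", "", labels)
  bad <- !grepl("[0-9]+$", clean)
  if (any(bad))
    stop("unparseable channel label(s), no trailing digits: ",
         paste(labels[bad], collapse = ", "))
  electrode <- sub("[0-9]+$", "", clean)
  contact <- as.integer(sub("^.*?([0-9]+)$", "\\1", clean))
  if (any(!nzchar(electrode)))
    stop("unparseable channel label(s), empty electrode prefix: ",
         paste(labels[!nzchar(electrode)], collapse = ", "))
  data.frame(label = labels, electrode = electrode, contact = contact,
             stringsAsFactors = FALSE)
}

#' Format an (electrode, contact) pair as a canonical label
#'
#' Serializes with 2-digit zero padding, e.g. \code{("LA", 1)} ->
#' \code{"LA01"}. \code{parseChannelLabel(formatChannelLabel(e, c))}
#' round-trips to \code{(e, c)}.
#'
#' @param electrode character vector of electrode prefixes.
#' @param contact integer vector of contact indices (>= 1).
#' @return character vector of labels.
#' @export
formatChannelLabel <- function(electrode, contact) {
  stopifnot(all(contact >= 1))
  sprintf("%s%02d", electrode, as.integer(contact))
}

#' Build a channel metadata table from labels
#'
#' Hemisphere is taken from the leading \code{L}/\code{R} letter of the
#' electrode name unless given explicitly. Channels localized to
#' cerebrospinal fluid are screened out (\code{retained = FALSE}): CSF
#' contacts do not record brain tissue and are excluded from analysis.
#'
#' @param labels channel labels.
#' @param hemisphere optional explicit hemisphere vector (\code{"L"},
#'   \code{"R"}, \code{"unknown"}); overrides the label-derived value.
#' @param tissue tissue class per channel: \code{"grey"}, \code{"white"},
#'   \code{"csf"} or \code{"unknown"}.
#' @return channel metadata \code{data.frame} (see
#'   \code{\link{IEEGRecording}}).
#' @export
makeChannelInfo <- function(labels, hemisphere = NULL, tissue = "unknown") {
  parsed <- parseChannelLabel(labels)
  if (is.null(hemisphere)) {
    lead <- substr(parsed$electrode, 1, 1)
    hemisphere <- ifelse(lead == "L", "L", ifelse(lead == "R", "R", "unknown"))
  }
  tissue <- rep_len(tissue, length(labels))
  stopifnot(all(tissue %in% c("grey", "white", "csf", "unknown")))
  data.frame(label = parsed$label, electrode = parsed$electrode,
             contact = parsed$contact,
             hemisphere = rep_len(hemisphere, length(labels)),
             tissue = tissue,
             retained = tissue != "csf",
             stringsAsFactors = FALSE)
}

## zero-phase application of a filter to every row of a channels x samples
## matrix
.filtRows <- function(filt, x) {
  out <- t(apply(x, 1, function(v) signal::filtfilt(filt, v)))
  dimnames(out) <- dimnames(x)
  out
}

#' Notch-filter a recording at the power-line frequency
#'
#' Fourth-order IIR (Butterworth band-stop, two second-order sections)
#' notch with a 2 Hz stop bandwidth, applied forward-backward so the net
#' filter is zero phase. Zero-phase application avoids montage-dependent
#' phase bias in phase-based connectivity measures.
#'
#' @param rec an \code{\link{IEEGRecording}}.
#' @param freqHz notch centre frequency (default 60 Hz).
#' @param bwHz stop bandwidth in Hz.
#' @return filtered \code{IEEGRecording} of the same shape.
#' @export
notchFilter <- function(rec, freqHz = 60, bwHz = 2) {
  fs <- rec@fs
  if (freqHz >= fs / 2)
    stop("notch frequency must be below the Nyquist frequency (fs/2)")
  edges <- c(freqHz - bwHz / 2, freqHz + bwHz / 2) / (fs / 2)
  filt <- signal::butter(2, edges, type = "stop")
  rec@data <- .filtRows(filt, rec@data)
  rec
}

#' Band-pass filter a recording
#'
#' Fourth-order Butterworth band-pass (order-2 prototype, 4 poles), applied
#' forward-backward (zero phase). If the upper edge reaches the Nyquist
#' frequency it is clipped to \code{0.9 * fs/2} with a warning, which
#' happens for the ripple band (80-250 Hz) at low sampling rates.
#'
#' @param rec an \code{\link{IEEGRecording}}.
#' @param low,high band edges in Hz (\code{0 < low < high}).
#' @return filtered \code{IEEGRecording}.
#' @export
bandpassFilter <- function(rec, low, high) {
  fs <- rec@fs
  stopifnot(low > 0, low < high)
  if (low >= fs / 2)
    stop("band infeasible: lower edge at or above Nyquist frequency")
  if (high >= fs / 2) {
    high <- 0.9 * fs / 2
    warning(sprintf("band upper edge clipped to %.1f Hz (0.9 x Nyquist)", high))
  }
  filt <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  rec@data <- .filtRows(filt, rec@data)
  rec
}

#' Select random non-overlapping epochs from a long recording
#'
#' Draws \code{nEpochs} disjoint epochs of \code{epochS} seconds uniformly
#' over feasible placements (rejection sampling) inside a local-time
#' window, reproducibly from \code{seed}. The study design samples five
#' random 2-minute interictal epochs between 13:00 and 15:00 local time,
#' when patients are most likely awake.
#'
#' @param rec a long \code{\link{IEEGRecording}} with a valid
#'   \code{epochStart} timestamp.
#' @param nEpochs number of epochs.
#' @param epochS epoch duration in seconds.
#' @param window local-time window as \code{c("HH:MM", "HH:MM")},
#'   half-open.
#' @param seed integer seed (mandatory for provenance).
#' @return an \code{\link{EpochSet}}; epochs are ordered by start time.
#' @export
selectEpochs <- function(rec, nEpochs = 5, epochS = 120,
                         window = c("13:00", "15:00"), seed) {
  stopifnot(!missing(seed))
  fs <- rec@fs
  n <- ncol(rec@data)
  epochSamp <- round(epochS * fs)

  ## feasible start samples: epoch fully inside the recording and inside
  ## the local-time window [w0, w1)
  day <- as.POSIXct(format(rec@epochStart, "%Y-%m-%d"),
                    tz = attr(rec@epochStart, "tzone") %||% "UTC")
  toSec <- function(hm) {
    p <- as.integer(strsplit(hm, ":")[[1]])
    p[1] * 3600 + p[2] * 60
  }
  recOffset <- as.numeric(difftime(rec@epochStart, day, units = "secs"))
  lo <- max(0, toSec(window[1]) - recOffset)
  hi <- min(n / fs, toSec(window[2]) - recOffset) - epochS
  loSamp <- ceiling(lo * fs)
  hiSamp <- floor(hi * fs)
  span <- (hiSamp - loSamp) / fs + epochS
  if (hiSamp < loSamp || span < nEpochs * epochS)
    stop(sprintf(paste0("insufficient data in window: %.1f s available, ",
                        "%d x %g s requested"),
                 max(span, 0), nEpochs, epochS))

  set.seed(as.integer(seed))
  starts <- integer(0)
  while (length(starts) < nEpochs) {
    cand <- loSamp + floor(stats::runif(1) * (hiSamp - loSamp + 1))
    if (all(abs(cand - starts) >= epochSamp)) starts <- c(starts, cand)
  }
  starts <- sort(starts)
  eps <- lapply(starts, function(s0) {
    e <- rec
    e@data <- rec@data[, (s0 + 1):(s0 + epochSamp), drop = FALSE]
    e@epochStart <- rec@epochStart + s0 / fs
    e
  })
  epochSet(eps, epochLength = epochS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## power in [lo, hi] Hz of one signal via periodogram
.bandPower <- function(v, fs, lo, hi) {
  n <- length(v)
  sp <- abs(stats::fft(v - mean(v)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  sum(sp[keep & f >= lo & f <= hi])
}

#' Reject artifact-dominated channels
#'
#' Applies two screening rules across all epochs of a set: (i) amplitude -
#' a channel whose absolute voltage exceeds \code{ampThreshUv} in more than
#' 1 percent of samples is rejected; (ii) line noise - a channel whose
#' power in a 2-Hz band around \code{lineHz} exceeds
#' \code{lineRatioThresh} times its broadband power is rejected. Rejected
#' channels get \code{retained = FALSE}; a rejection report is attached as
#' the \code{"rejection"} attribute.
#'
#' Default thresholds (500 uV, ratio 0.5) are explicit configuration, not
#' claims about any particular clinical dataset.
#'
#' @param es an \code{\link{EpochSet}}.
#' @param ampThreshUv amplitude threshold in microvolts.
#' @param lineRatioThresh line-power to broadband-power ratio threshold.
#' @param lineHz power-line frequency.
#' @return the \code{EpochSet} with updated \code{retained} flags.
#' @export
rejectArtifactChannels <- function(es, ampThreshUv = 500,
                                   lineRatioThresh = 0.5, lineHz = 60) {
  stopifnot(ampThreshUv > 0, lineRatioThresh > 0)
  X <- do.call(cbind, lapply(es@epochs, function(e) e@data))
  fs <- es@epochs[[1]]@fs
  ampFrac <- rowMeans(abs(X) > ampThreshUv)
  lineRatio <- apply(X, 1, function(v) {
    tot <- .bandPower(v, fs, 0, fs / 2)
    if (tot <= 0) return(0)
    .bandPower(v, fs, lineHz - 1, lineHz + 1) / tot
  })
  ampRej <- ampFrac > 0.01
  lineRej <- lineRatio > lineRatioThresh
  rej <- ampRej | lineRej
  report <- data.frame(label = es@epochs[[1]]@channels$label,
                       amp_frac = ampFrac, line_ratio = lineRatio,
                       rejected_amplitude = ampRej,
                       rejected_line = lineRej, stringsAsFactors = FALSE)
  es@epochs <- lapply(es@epochs, function(e) {
    e@channels$retained <- e@channels$retained & !rej
    e
  })
  if (!any(es@epochs[[1]]@channels$retained))
    warning("all channels rejected during artifact screening")
  attr(es, "rejection") <- report
  es
}

#' Read a recording from a plain numeric array container
#'
#' Reads a channels x samples matrix from a delimited text file (one row
#' per channel) and a sidecar channel-metadata CSV with columns
#' \code{label}, \code{electrode}, \code{contact}, \code{hemisphere},
#' \code{tissue}.
#'
#' @param dataFile path to the numeric matrix (CSV, no header).
#' @param metaFile path to the channel metadata CSV.
#' @param fs sampling rate in Hz.
#' @param ... passed to \code{\link{ieegRecording}}.
#' @return an \code{\link{IEEGRecording}} with \code{scheme = "machine"}.
#' @export
readRecordingCSV <- function(dataFile, metaFile, fs, ...) {
  X <- as.matrix(utils::read.csv(dataFile, header = FALSE))
  meta <- utils::read.csv(metaFile, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "hemisphere", "tissue") %in% names(meta)))
  info <- makeChannelInfo(meta$label, hemisphere = meta$hemisphere,
                          tissue = meta$tissue)
  ieegRecording(X, fs = fs, channels = info, ...)
}
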