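#' Common average re-referencing
#'
#' Subtracts, at every sample, the mean over retained grey/white-matter
#' channels from each retained channel. The machine reference is a shared
#' additive term on every channel, so CAR cancels it exactly. Non-retained
#' channels are excluded both from the mean and from the output.
#'
#' @param rec an \code{\link{IEEGRecording}} (any scheme; typically
#'   \code{"machine"}).
#' @return an \code{IEEGRecording} with \code{scheme = "car"}, containing
#'   only the retained channels; every column of the output has mean zero.
#' @export
commonAverage <- function(rec) {
  info <- rec@channels
  keep <- which(info$retained & info$tissue %in% c("grey", "white", "unknown"))
  if (length(keep) < 2)
    stop("common average reference requires >= 2 retained grey/white channels")
  X <- rec@data[keep, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  out <- rec
  out@data <- X
  out@channels <- info[keep, , drop = FALSE]
  rownames(out@channels) <- NULL
  out@scheme <- "car"
  out
}

#' Enumerate bipolar derived channels
#'
#' Within each electrode, retained contacts are sorted by contact index and
#' each contact is paired with the next retained contact provided the index
#' gap is at most \code{maxSkip + 1} - by default one missing intermediate
#' contact may be skipped (\code{LA01-LA03} is allowed when LA02 is
#' missing). Pairs never cross electrodes. Derived channels are named
#' \code{"<low>-<high>"}, inherit hemisphere/tissue from the lower-numbered
#' (anchor) parent, and carry signal \code{low - high}.
#'
#' @param channels channel metadata \code{data.frame} (see
#'   \code{\link{makeChannelInfo}}).
#' @param maxSkip maximum number of missing intermediate contacts that may
#'   be skipped (default 1).
#' @return \code{data.frame} with columns \code{name}, \code{parent1},
#'   \code{parent2}, \code{electrode}, \code{hemisphere}, \code{tissue},
#'   \code{anchor}; zero rows when no pairs exist.
#' @export
bipolarPairs <- function(channels, maxSkip = 1) {
  out <- list()
  for (el in unique(channels$electrode)) {
    sub <- channels[channels$electrode == el & channels$retained, , drop = FALSE]
    sub <- sub[order(sub$contact), , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      gap <- sub$contact[i + 1] - sub$contact[i]
      if (gap <= maxSkip + 1)
        out[[length(out) + 1]] <- data.frame(
          name = paste0(sub$label[i], "-", sub$label[i + 1]),
          parent1 = sub$label[i], parent2 = sub$label[i + 1],
          electrode = el, hemisphere = sub$hemisphere[i],
          tissue = sub$tissue[i], anchor = sub$label[i],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(name = character(0), parent1 = character(0),
                      parent2 = character(0), electrode = character(0),
                      hemisphere = character(0), tissue = character(0),
                      anchor = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Apply a reference scheme to a recording
#'
#' \code{"machine"} returns the input unchanged; \code{"car"} applies
#' \code{\link{commonAverage}}; \code{"bipolar"} builds the
#' \code{\link{bipolarPairs}} montage and subtracts the higher-numbered
#' parent from the lower-numbered one (polarity: low minus high). Both CAR
#' and bipolar montages exactly cancel any waveform added identically to
#' all channels.
#'
#' @param rec an \code{\link{IEEGRecording}}.
#' @param scheme \code{"machine"}, \code{"car"} or \code{"bipolar"}.
#' @param maxSkip passed to \code{\link{bipolarPairs}}.
#' @return re-referenced \code{IEEGRecording}. For bipolar output the
#'   channel table describes the derived channels (contact = anchor
#'   contact) and the montage map is attached as attribute
#'   \code{"montage"}.
#' @export
applyReference <- function(rec, scheme = c("machine", "car", "bipolar"),
                           maxSkip = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "machine") return(rec)
  if (scheme == "car") return(commonAverage(rec))
  pairs <- bipolarPairs(rec@channels, maxSkip = maxSkip)
  if (!nrow(pairs))
    stop("bipolar montage is empty: no electrode has >= 2 retained contacts")
  i1 <- match(pairs$parent1, rec@channels$label)
  i2 <- match(pairs$parent2, rec@channels$label)
  X <- rec@data[i1, , drop = FALSE] - rec@data[i2, , drop = FALSE]
  rownames(X) <- pairs$name
  anchorContact <- parseChannelLabel(pairs$anchor)$contact
  info <- data.frame(label = pairs$name, electrode = pairs$electrode,
                     contact = anchorContact, hemisphere = pairs$hemisphere,
                     tissue = pairs$tissue, retained = TRUE,
                     stringsAsFactors = FALSE)
  out <- rec
  out@data <- X
  out@channels <- info
  out@scheme <- "bipolar"
  attr(out, "montage") <- pairs
  out
}

#' Apply a reference scheme to every epoch of a set
#' @param es an \code{\link{EpochSet}}.
#' @inheritParams applyReference
#' @return a re-referenced \code{\link{EpochSet}}.
#' @export
applyReferenceEpochs <- function(es, scheme, maxSkip = 1) {
  es@epochs <- lapply(es@epochs, applyReference, scheme = scheme,
                      maxSkip = maxSkip)
  es
}
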