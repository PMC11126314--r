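#' Canonical frequency bands
#'
#' The seven canonical iEEG bands: delta (0.5-4), theta (4-8), alpha
#' (8-12), beta (12-30), gamma (30-80), ripple (80-250) and broadband
#' (0.5-250 Hz).
#'
#' @return \code{data.frame} with columns \code{name}, \code{low},
#'   \code{high}.
#' @export
bandTable <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma", "ripple", "broadband"),
    low  = c(0.5, 4, 8, 12, 30, 80, 0.5),
    high = c(4, 8, 12, 30, 80, 250, 250),
    stringsAsFactors = FALSE)
}

.bandSpec <- function(band) {
  tb <- bandTable()
  i <- match(band, tb$name)
  if (is.na(i)) stop("unknown band: ", band)
  tb[i, ]
}

#' Enumerate the pre-processing pipeline suite
#'
#' Full enumeration of reference x measure x band combinations: per
#' reference, 3 time-domain measures (Pearson, squared Pearson,
#' cross-correlation) plus 3 spectral/amplitude measures (coherence, PLV,
#' relative entropy) x 7 bands = 24 connectivity methods; with 2 reference
#' schemes this yields 48 pipelines.
#'
#' @param schemes reference schemes to enumerate (default CAR and bipolar).
#' @return \code{data.frame} with columns \code{key}, \code{scheme},
#'   \code{measure}, \code{band} (NA for time-domain measures).
#' @export
pipelineSpecs <- function(schemes = c("car", "bipolar")) {
  bands <- bandTable()$name
  rows <- list()
  for (s in schemes) {
    for (m in c("pearson", "pearson_sq", "xcorr"))
      rows[[length(rows) + 1]] <- data.frame(scheme = s, measure = m,
                                             band = NA_character_)
    for (m in c("coh", "plv", "re"))
      for (b in bands)
        rows[[length(rows) + 1]] <- data.frame(scheme = s, measure = m,
                                               band = b)
  }
  out <- do.call(rbind, rows)
  out$key <- ifelse(is.na(out$band), paste(out$scheme, out$measure, sep = "-"),
                    paste(out$scheme, out$measure, out$band, sep = "-"))
  out[, c("key", "scheme", "measure", "band")]
}

## non-overlapping consecutive window index sets; trailing remainder dropped
.windowStarts <- function(nSamples, fs, windowS = 2) {
  wlen <- round(windowS * fs)
  if (nSamples < wlen)
    stop(sprintf("epoch (%d samples) shorter than one %g-s window",
                 nSamples, windowS))
  seq(1L, nSamples - wlen + 1L, by = wlen)
}

#' Split a recording into analysis windows
#'
#' Non-overlapping consecutive windows of \code{windowS} seconds; the
#' trailing remainder shorter than one window is dropped. A 120-s epoch at
#' 2-s windows yields 60 windows.
#'
#' @param rec an \code{\link{IEEGRecording}}.
#' @param windowS window length in seconds (default 2, chosen to
#'   approximate local stationarity).
#' @return list of channels x window-samples matrices.
#' @export
windowSignal <- function(rec, windowS = 2) {
  wlen <- round(windowS * rec@fs)
  starts <- .windowStarts(ncol(rec@data), rec@fs, windowS)
  lapply(starts, function(s) rec@data[, s:(s + wlen - 1L), drop = FALSE])
}

.anchorsOf <- function(rec) {
  labs <- rec@channels$label
  ifelse(grepl("-", labs), sub("-.*$", "", labs), labs)
}

.netFromMatrix <- function(W, rec, measure, band = NA_character_,
                           nWindows = 0) {
  connectivityNetwork(W, nodes = rec@channels$label, measure = measure,
                      band = band, scheme = rec@scheme, nWindows = nWindows,
                      anchors = .anchorsOf(rec))
}

## running mean of per-window pair matrices with NA (undefined) exclusion
.meanFinite <- function(mats) {
  sum_ <- Reduce(`+`, lapply(mats, function(m) ifelse(is.finite(m), m, 0)))
  cnt <- Reduce(`+`, lapply(mats, function(m) is.finite(m) + 0))
  out <- sum_ / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Pearson and squared-Pearson connectivity
#'
#' Pairwise Pearson correlation computed within each 2-s window and
#' averaged across windows. The signed variant averages r; the squared
#' variant averages r^2 per window. Windows in which a channel has zero
#' variance contribute no value for that channel's pairs.
#'
#' @param rec an \code{\link{IEEGRecording}} (one epoch).
#' @param windowS window length in seconds.
#' @param squared if TRUE return squared Pearson (r^2 averaged).
#' @return a \code{\link{ConnectivityNetwork}}.
#' @export
pearsonNetwork <- function(rec, windowS = 2, squared = FALSE) {
  wins <- windowSignal(rec, windowS)
  mats <- lapply(wins, function(Xw) {
    C <- suppressWarnings(stats::cor(t(Xw)))
    if (squared) C^2 else C
  })
  W <- .meanFinite(mats)
  .netFromMatrix(W, rec, if (squared) "pearson_sq" else "pearson",
                 nWindows = length(wins))
}

## FFT-based normalized cross-correlation maximum over |lag| <= maxLag
.xcorrMax <- function(Xw, maxLag) {
  nch <- nrow(Xw); wlen <- ncol(Xw)
  Xc <- Xw - rowMeans(Xw)
  sds <- sqrt(rowMeans(Xc^2))
  nfft <- 2^ceiling(log2(wlen + maxLag + 1))
  P <- matrix(0, nfft, nch)
  P[seq_len(wlen), ] <- t(Xc)
  F <- stats::mvfft(P)
  lags <- -maxLag:maxLag
  ovl <- wlen - abs(lags)
  W <- matrix(NA_real_, nch, nch)
  for (i in seq_len(nch - 1)) for (j in (i + 1):nch) {
    if (sds[i] == 0 || sds[j] == 0) next
    cc <- Re(stats::fft(F[, i] * Conj(F[, j]), inverse = TRUE)) / nfft
    ## circular index: lag tau -> cc[tau + 1] for tau >= 0, cc[nfft + tau + 1]
    ## for tau < 0 (zero padding prevents wrap-around)
    vals <- cc[ifelse(lags >= 0, lags + 1, nfft + lags + 1)]
    r <- vals / (ovl * sds[i] * sds[j])
    W[i, j] <- W[j, i] <- max(abs(r))
  }
  W
}

#' Cross-correlation connectivity
#'
#' Per window, the maximum over time lags |tau| <= \code{maxLagMs} of the
#' absolute normalized cross-correlation (signals demeaned per window;
#' normalization by the product of the window standard deviations and the
#' overlap length), averaged across windows. Values lie in [0, 1].
#'
#' @inheritParams pearsonNetwork
#' @param maxLagMs maximum lag in milliseconds (default 200).
#' @return a \code{\link{ConnectivityNetwork}}.
#' @export
xcorrNetwork <- function(rec, windowS = 2, maxLagMs = 200) {
  if (maxLagMs >= windowS * 1000)
    stop("maxLagMs must be smaller than the window length")
  maxLag <- round(maxLagMs / 1000 * rec@fs)
  wins <- windowSignal(rec, windowS)
  mats <- lapply(wins, .xcorrMax, maxLag = maxLag)
  W <- pmin(.meanFinite(mats), 1)
  .netFromMatrix(W, rec, "xcorr", nWindows = length(wins))
}

## Hann-tapered auto/cross spectra averaged across windows of one epoch
.crossSpectra <- function(X, fs, windowS = 2, overlap = 0) {
  wlen <- round(windowS * fs)
  step <- max(1L, round(wlen * (1 - overlap)))
  if (ncol(X) < wlen) stop("signal shorter than one spectral window")
  starts <- seq(1L, ncol(X) - wlen + 1L, by = step)
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, wlen - 1) / (wlen - 1)))
  nch <- nrow(X)
  pairs <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  nbin <- floor(wlen / 2) + 1L
  Sxx <- matrix(0, nbin, nch)
  Sxy <- matrix(0 + 0i, nbin, nrow(pairs))
  for (s in starts) {
    seg <- t(X[, s:(s + wlen - 1L), drop = FALSE])
    seg <- sweep(seg, 2, colMeans(seg)) * taper
    F <- stats::mvfft(seg)[seq_len(nbin), , drop = FALSE]
    Sxx <- Sxx + abs(F)^2
    Sxy <- Sxy + F[, pairs[, 1], drop = FALSE] * Conj(F[, pairs[, 2],
                                                       drop = FALSE])
  }
  list(freq = (seq_len(nbin) - 1) * fs / wlen, Sxx = Sxx, Sxy = Sxy,
       pairs = pairs, K = length(starts), nch = nch)
}

.coherenceFromSpectra <- function(cs, low, high, squared = TRUE) {
  mask <- cs$freq >= low & cs$freq <= high
  if (!any(mask)) stop("no frequency bins inside the requested band")
  msc <- abs(cs$Sxy[mask, , drop = FALSE])^2 /
    (cs$Sxx[mask, cs$pairs[, 1], drop = FALSE] *
     cs$Sxx[mask, cs$pairs[, 2], drop = FALSE])
  vals <- colMeans(if (squared) msc else sqrt(msc))
  W <- matrix(NA_real_, cs$nch, cs$nch)
  W[cs$pairs] <- vals
  W[cs$pairs[, c(2, 1), drop = FALSE]] <- vals
  W
}

#' Coherence connectivity
#'
#' Hann-tapered periodograms are computed per 2-s window, auto- and
#' cross-spectra are averaged across all windows of the epoch, and the
#' per-bin magnitude-squared coherence |Sxy|^2 / (Sxx Syy) is averaged
#' over the bins inside the requested band. Coherence from a single
#' segment is identically 1, so at least two windows are required.
#'
#' @inheritParams pearsonNetwork
#' @param band band name (see \code{\link{bandTable}}).
#' @param squared if FALSE, report magnitude coherence (square root of the
#'   magnitude-squared coherence per bin) instead.
#' @return a \code{\link{ConnectivityNetwork}} with measure \code{"coh"}.
#' @export
coherenceNetwork <- function(rec, band, windowS = 2, squared = TRUE) {
  bs <- .bandSpec(band)
  cs <- .crossSpectra(rec@data, rec@fs, windowS)
  if (cs$K < 2)
    stop("coherence requires >= 2 windows (one segment gives coherence 1)")
  W <- .coherenceFromSpectra(cs, bs$low, min(bs$high, rec@fs / 2),
                             squared = squared)
  .netFromMatrix(W, rec, "coh", band = band, nWindows = cs$K)
}

## analytic signal via one-sided FFT doubling
.analytic <- function(v) {
  n <- length(v)
  F <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(F * h, inverse = TRUE) / n
}

.plvFromFiltered <- function(Xf, fs, windowS) {
  Z <- apply(Xf, 1, function(v) {
    a <- .analytic(v)
    a / pmax(Mod(a), .Machine$double.eps)
  })                                   # samples x channels, unit-modulus
  starts <- .windowStarts(ncol(Xf), fs, windowS)
  wlen <- round(windowS * fs)
  mats <- lapply(starts, function(s) {
    zw <- Z[s:(s + wlen - 1L), , drop = FALSE]
    G <- Mod(crossprod(Conj(zw), zw)) / wlen
    G <- (G + t(G)) / 2                # remove BLAS rounding asymmetry
    diag(G) <- NA_real_
    G
  })
  list(W = pmin(.meanFinite(mats), 1), nWindows = length(mats))
}

#' Phase locking value connectivity
#'
#' Signals are band-pass filtered, instantaneous phases extracted from the
#' analytic signal, and per window the PLV is the modulus of the mean
#' complex phase difference across samples; window PLVs are averaged.
#' PLV is 1 for a constant phase lag and tends to the estimator floor for
#' independent phases.
#'
#' @inheritParams coherenceNetwork
#' @return a \code{\link{ConnectivityNetwork}} with measure \code{"plv"}.
#' @export
plvNetwork <- function(rec, band, windowS = 2) {
  bs <- .bandSpec(band)
  frec <- bandpassFilter(rec, bs$low, bs$high)
  r <- .plvFromFiltered(frec@data, rec@fs, windowS)
  .netFromMatrix(r$W, rec, "plv", band = band, nWindows = r$nWindows)
}

## discretized KL divergence of two samples on shared equal-width bins
.klPair <- function(x, y, nBins) {
  lo <- min(x, y); hi <- max(x, y)
  if (hi <= lo) return(0)
  binw <- (hi - lo) / nBins
  ix <- pmin.int(nBins, pmax.int(1L, ceiling((x - lo) / binw)))
  iy <- pmin.int(nBins, pmax.int(1L, ceiling((y - lo) / binw)))
  p <- tabulate(ix, nBins) + 0.5
  q <- tabulate(iy, nBins) + 0.5
  p <- p / sum(p); q <- q / sum(q)
  max(sum(p * log(p / q)), sum(q * log(q / p)))
}

.reFromFiltered <- function(Xf, fs, windowS, nBins) {
  starts <- .windowStarts(ncol(Xf), fs, windowS)
  wlen <- round(windowS * fs)
  nch <- nrow(Xf)
  mats <- lapply(starts, function(s) {
    Xw <- Xf[, s:(s + wlen - 1L), drop = FALSE]
    W <- matrix(NA_real_, nch, nch)
    for (i in seq_len(nch - 1)) for (j in (i + 1):nch)
      W[i, j] <- W[j, i] <- .klPair(Xw[i, ], Xw[j, ], nBins)
    W
  })
  list(W = .meanFinite(mats), nWindows = length(mats))
}

#' Relative entropy (KL-divergence) connectivity
#'
#' An amplitude-distribution measure: per window and channel pair, both
#' band-passed signals are histogrammed into \code{nBins} equal-width bins
#' spanning the pooled min-max of the pair, counts are smoothed by adding
#' one half, and the Kullback-Leibler divergence is computed in both
#' directions; the larger direction is kept (RE is asymmetric). Window
#' values are averaged. RE is insensitive to sample ordering: permuting a
#' signal's samples leaves its amplitude distribution, hence RE,
#' unchanged. Higher RE means more dissimilar amplitude distributions,
#' i.e. lower functional connectivity.
#'
#' @inheritParams coherenceNetwork
#' @param nBins number of histogram bins (default 10).
#' @return a \code{\link{ConnectivityNetwork}} with measure \code{"re"}.
#' @export
relativeEntropyNetwork <- function(rec, band, windowS = 2, nBins = 10) {
  stopifnot(nBins >= 2)
  bs <- .bandSpec(band)
  frec <- bandpassFilter(rec, bs$low, bs$high)
  r <- .reFromFiltered(frec@data, rec@fs, windowS, nBins)
  .netFromMatrix(r$W, rec, "re", band = band, nWindows = r$nWindows)
}

#' Positivity transforms for relative-entropy networks
#'
#' RE is non-negative but plays the role of an inverse connectivity; two
#' transforms are provided for analyses that require a positive
#' similarity-like scale: \code{"abs"} (absolute value, identity on valid
#' RE) and \code{"inverse_one_plus"}, the monotone-decreasing map
#' 1 / (1 + x).
#'
#' @param net a \code{\link{ConnectivityNetwork}} with measure \code{"re"}.
#' @param mode \code{"abs"} or \code{"inverse_one_plus"}.
#' @return the transformed network (same measure id).
#' @export
transformRE <- function(net, mode = c("abs", "inverse_one_plus")) {
  mode <- match.arg(mode)
  if (net@measure != "re")
    stop("transformRE applies only to relative-entropy networks")
  W <- net@weights
  net@weights <- switch(mode, abs = abs(W), inverse_one_plus = 1 / (1 + W))
  net
}

#' Compute one connectivity network from a single epoch
#' @param rec re-referenced epoch.
#' @param measure measure id.
#' @param band band name (spectral measures only).
#' @param windowS,maxLagMs,reBins,cohSquared estimator settings.
#' @return a \code{\link{ConnectivityNetwork}}.
#' @export
epochNetwork <- function(rec, measure, band = NA, windowS = 2,
                         maxLagMs = 200, reBins = 10, cohSquared = TRUE) {
  switch(measure,
    pearson = pearsonNetwork(rec, windowS, squared = FALSE),
    pearson_sq = pearsonNetwork(rec, windowS, squared = TRUE),
    xcorr = xcorrNetwork(rec, windowS, maxLagMs),
    coh = coherenceNetwork(rec, band, windowS, squared = cohSquared),
    plv = plvNetwork(rec, band, windowS),
    re = relativeEntropyNetwork(rec, band, windowS, nBins = reBins),
    stop("unknown measure: ", measure))
}

#' Element-wise average of per-epoch networks
#' @param nets list of \code{\link{ConnectivityNetwork}} objects with equal
#'   nodes and spec.
#' @return the averaged \code{ConnectivityNetwork}.
#' @export
averageNetworks <- function(nets) {
  stopifnot(length(nets) >= 1)
  W <- .meanFinite(lapply(nets, function(n) n@weights))
  out <- nets[[1]]
  diag(W) <- NA_real_
  out@weights <- W
  out@nWindows <- sum(vapply(nets, function(n) n@nWindows, 0))
  out
}

#' Run the full pre-processing pipeline suite
#'
#' Applies every requested reference scheme to each epoch, computes all 24
#' connectivity methods per scheme (3 time-domain + 3 banded x 7 bands)
#' and averages the per-epoch networks element-wise, yielding one network
#' per pipeline (48 with both schemes). Band-pass filtering is shared
#' between PLV and RE of the same band, and cross-spectra are computed
#' once per epoch for all coherence bands. A pipeline whose montage or
#' estimator fails is dropped with a warning; the remaining pipelines
#' proceed.
#'
#' @param es a cleaned \code{\link{EpochSet}}.
#' @param schemes reference schemes.
#' @param windowS analysis window (s).
#' @param maxSkip bipolar skip allowance.
#' @param maxLagMs cross-correlation maximum lag (ms).
#' @param reBins relative-entropy histogram bins.
#' @param cohSquared report magnitude-squared (TRUE) or magnitude
#'   coherence.
#' @return named list of \code{\link{ConnectivityNetwork}} objects keyed as
#'   in \code{\link{pipelineSpecs}}.
#' @export
runPipelineSuite <- function(es, schemes = c("car", "bipolar"), windowS = 2,
                             maxSkip = 1, maxLagMs = 200, reBins = 10,
                             cohSquared = TRUE) {
  specs <- pipelineSpecs(schemes)
  out <- list()
  for (s in schemes) {
    res <- try(applyReferenceEpochs(es, s, maxSkip = maxSkip), silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("reference scheme ", s, " failed: ", attr(res, "condition")$message)
      next
    }
    perEpoch <- lapply(res@epochs, function(ep) {
      nets <- list()
      nets[["pearson"]] <- pearsonNetwork(ep, windowS, squared = FALSE)
      nets[["pearson_sq"]] <- pearsonNetwork(ep, windowS, squared = TRUE)
      nets[["xcorr"]] <- xcorrNetwork(ep, windowS, maxLagMs)
      cspec <- .crossSpectra(ep@data, ep@fs, windowS)
      for (b in bandTable()$name) {
        bs <- .bandSpec(b)
        W <- .coherenceFromSpectra(cspec, bs$low, min(bs$high, ep@fs / 2),
                                   squared = cohSquared)
        nets[[paste("coh", b, sep = "-")]] <-
          .netFromMatrix(W, ep, "coh", band = b, nWindows = cspec$K)
        frec <- suppressWarnings(bandpassFilter(ep, bs$low, bs$high))
        pl <- .plvFromFiltered(frec@data, ep@fs, windowS)
        nets[[paste("plv", b, sep = "-")]] <-
          .netFromMatrix(pl$W, ep, "plv", band = b, nWindows = pl$nWindows)
        re <- .reFromFiltered(frec@data, ep@fs, windowS, reBins)
        nets[[paste("re", b, sep = "-")]] <-
          .netFromMatrix(re$W, ep, "re", band = b, nWindows = re$nWindows)
      }
      nets
    })
    for (nm in names(perEpoch[[1]])) {
      key <- paste(s, nm, sep = "-")
      out[[key]] <- averageNetworks(lapply(perEpoch, `[[`, nm))
    }
  }
  ## order as in pipelineSpecs
  out[specs$key[specs$key %in% names(out)]]
}
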