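#' Configuration for the synthetic iEEG cohort generator
#'
#' Emulates the study's data model: bilateral mirrored SEEG montages (up
#' to 3 lateral depth electrodes per hemisphere, up to 12 contacts each,
#' at most 72 channels), pink background activity, band-limited shared
#' oscillations inducing exp(-corrDecay * distance) within-electrode
#' correlation, a machine-reference contamination source added identically
#' to every channel, spike-like biphasic transients, artifact channels,
#' and configurable hemispheric asymmetries targeted at specific measure
#' families (amplitude-distribution gains for relative entropy; coupling
#' gain for coherence/PLV).
#'
#' @param nPatients cohort size.
#' @param electrodesPerHemisphere number of depth electrodes per
#'   hemisphere (<= 3).
#' @param contactsPerElectrode contacts per electrode (<= 12).
#' @param fs sampling rate (Hz).
#' @param nEpochs,epochS epochs per patient and epoch length (s); default
#'   five 2-minute epochs.
#' @param channelSdUv target per-channel signal standard deviation
#'   (microvolts).
#' @param oscWeight fraction (amplitude) of channel variance carried by
#'   the band-limited oscillatory field.
#' @param oscBand frequency band of the shared oscillations (Hz).
#' @param refContaminationVar variance (uV^2) of the common reference
#'   source; default one third of the channel variance.
#' @param corrDecay exponential decay rate of within-electrode correlation
#'   per contact spacing.
#' @param sozSides per-patient SOZ side (\code{"L"}/\code{"R"}); default
#'   alternates.
#' @param reGainSd log-sd of per-channel amplitude gains applied on the
#'   SOZ side; elevates amplitude-distribution divergence (relative
#'   entropy) while leaving scale-invariant measures untouched. 0 = off.
#' @param cohGainFactor multiplier on the oscillatory coupling weight on
#'   the SOZ side (1 = off; < 1 lowers SOZ-side coherence/PLV).
#' @param spikeRate spike transients per channel-minute.
#' @param sozSpikeFactor spike-rate multiplier on the SOZ side.
#' @param spikeAmpUv spike amplitude (microvolts).
#' @param artifactChannelFraction fraction of channels replaced by
#'   line-noise-dominated artifact channels.
#' @param seed integer master seed; every patient derives a sub-seed.
#' @return list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(nPatients = 20, electrodesPerHemisphere = 2,
                         contactsPerElectrode = 6, fs = 512, nEpochs = 5,
                         epochS = 120, channelSdUv = 50, oscWeight = 0.6,
                         oscBand = c(4, 30),
                         refContaminationVar = channelSdUv^2 / 3,
                         corrDecay = 1, sozSides = NULL, reGainSd = 0,
                         cohGainFactor = 1, spikeRate = 1,
                         sozSpikeFactor = 2, spikeAmpUv = 150,
                         artifactChannelFraction = 0, seed = 1) {
  stopifnot(electrodesPerHemisphere >= 1, electrodesPerHemisphere <= 3,
            contactsPerElectrode >= 2, contactsPerElectrode <= 12)
  nCh <- 2 * electrodesPerHemisphere * contactsPerElectrode
  if (nCh > 72) stop("montage exceeds 72 channels")
  if (is.null(sozSides))
    sozSides <- rep(c("L", "R"), length.out = nPatients)
  stopifnot(length(sozSides) == nPatients, all(sozSides %in% c("L", "R")))
  structure(list(nPatients = nPatients,
                 electrodesPerHemisphere = electrodesPerHemisphere,
                 contactsPerElectrode = contactsPerElectrode, fs = fs,
                 nEpochs = nEpochs, epochS = epochS,
                 channelSdUv = channelSdUv, oscWeight = oscWeight,
                 oscBand = oscBand,
                 refContaminationVar = refContaminationVar,
                 corrDecay = corrDecay, sozSides = sozSides,
                 reGainSd = reGainSd, cohGainFactor = cohGainFactor,
                 spikeRate = spikeRate, sozSpikeFactor = sozSpikeFactor,
                 spikeAmpUv = spikeAmpUv,
                 artifactChannelFraction = artifactChannelFraction,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

## pink (1/f amplitude) noise via spectral shaping, unit sd
.pinkNoise <- function(n) {
  F <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  F <- F / sqrt(f)
  v <- Re(stats::fft(F, inverse = TRUE)) / n
  v / stats::sd(v)
}

## biphasic spike transient: 70 ms sharp wave followed by a 300 ms slow wave
.spikeWave <- function(fs) {
  t1 <- seq(0, 0.07, by = 1 / fs)
  sharp <- sin(2 * pi * t1 / 0.07)
  t2 <- seq(0, 0.3, by = 1 / fs)
  slow <- -0.4 * sin(pi * t2 / 0.3)
  c(sharp, slow)
}

.mirrorMontage <- function(cfg) {
  els <- LETTERS[seq_len(cfg$electrodesPerHemisphere)]
  labels <- c(
    unlist(lapply(els, function(e)
      formatChannelLabel(paste0("L", e), seq_len(cfg$contactsPerElectrode)))),
    unlist(lapply(els, function(e)
      formatChannelLabel(paste0("R", e), seq_len(cfg$contactsPerElectrode)))))
  makeChannelInfo(labels, tissue = "grey")
}

#' Generate one synthetic patient
#'
#' @param cfg a \code{\link{cohortConfig}}.
#' @param patientIndex 1-based patient index (determines the sub-seed and
#'   SOZ side).
#' @return list with \code{epochs} (an \code{\link{EpochSet}}),
#'   \code{channels} (metadata), and \code{truth} (SOZ side, per-channel
#'   gains, artifact channels, spike times per epoch).
#' @export
generatePatient <- function(cfg, patientIndex) {
  stopifnot(inherits(cfg, "cohortConfig"))
  seed <- as.integer((cfg$seed + patientIndex * 131071) %% 2147483647L)
  set.seed(seed)
  info <- .mirrorMontage(cfg)
  nCh <- nrow(info)
  m <- cfg$contactsPerElectrode
  n <- round(cfg$epochS * cfg$fs)
  sozSide <- cfg$sozSides[patientIndex]
  isSoz <- info$hemisphere == sozSide

  gains <- rep(1, nCh)
  if (cfg$reGainSd > 0)
    gains[isSoz] <- exp(stats::rnorm(sum(isSoz), sd = cfg$reGainSd))
  w <- rep(cfg$oscWeight, nCh)
  w[isSoz] <- pmin(1, w[isSoz] * cfg$cohGainFactor)

  nArt <- round(cfg$artifactChannelFraction * nCh)
  artifactIdx <- if (nArt > 0) sort(sample(nCh, nArt)) else integer(0)

  Cmat <- exp(-cfg$corrDecay * abs(outer(seq_len(m), seq_len(m), `-`)))
  L <- t(chol(Cmat))
  elGroups <- split(seq_len(nCh), info$electrode)
  spike <- .spikeWave(cfg$fs)
  bp <- signal::butter(2, cfg$oscBand / (cfg$fs / 2), type = "pass")

  spikeTruth <- vector("list", cfg$nEpochs)
  eps <- lapply(seq_len(cfg$nEpochs), function(ei) {
    X <- matrix(0, nCh, n)
    for (idx in elGroups) {
      stopifnot(length(idx) == m)
      mixP <- L %*% matrix(stats::rnorm(m * n), m, n)
      pink <- t(apply(mixP, 1, function(v) {
        F <- stats::fft(v)
        f <- pmin(c(1, seq_len(n - 1)), c(1, rev(seq_len(n - 1))))
        u <- Re(stats::fft(F / sqrt(f), inverse = TRUE)) / n
        u / stats::sd(u)
      }))
      mixO <- L %*% matrix(stats::rnorm(m * n), m, n)
      osc <- t(apply(mixO, 1, function(v) {
        u <- signal::filtfilt(bp, v)
        u / stats::sd(u)
      }))
      wi <- w[idx]
      X[idx, ] <- sqrt(1 - wi^2) * pink + wi * osc
    }
    X <- cfg$channelSdUv * gains * X
    if (cfg$refContaminationVar > 0) {
      r <- .pinkNoise(n) * sqrt(cfg$refContaminationVar)
      X <- X + matrix(r, nCh, n, byrow = TRUE)
    }
    ## spike-like transients, rate elevated on the SOZ side
    spk <- vector("list", nCh)
    if (cfg$spikeRate > 0) {
      rates <- cfg$spikeRate * ifelse(isSoz, cfg$sozSpikeFactor, 1)
      for (ci in seq_len(nCh)) {
        k <- stats::rpois(1, rates[ci] * cfg$epochS / 60)
        if (k > 0) {
          starts <- sort(sample(n - length(spike), k))
          for (s0 in starts) {
            rng <- s0:(s0 + length(spike) - 1)
            X[ci, rng] <- X[ci, rng] + cfg$spikeAmpUv * spike
          }
          spk[[ci]] <- starts
        }
      }
    }
    if (length(artifactIdx)) {
      tt <- seq_len(n) / cfg$fs
      for (ci in artifactIdx)
        X[ci, ] <- 200 * sin(2 * pi * 60 * tt) +
          20 * stats::rnorm(n)
    }
    spikeTruth[[ei]] <<- spk
    ieegRecording(X, fs = cfg$fs, channels = info,
                  epochStart = as.POSIXct("2000-01-01 13:00:00", tz = "UTC") +
                    (ei - 1) * cfg$epochS)
  })
  list(epochs = epochSet(eps, cfg$epochS), channels = info,
       truth = list(sozSide = sozSide, gains = gains,
                    artifactChannels = info$label[artifactIdx],
                    spikeTimes = spikeTruth, seed = seed))
}

#' Generate a synthetic cohort with ground truth
#'
#' @param cfg a \code{\link{cohortConfig}}.
#' @param writeDir optional directory; when given, each patient's epochs
#'   are written as CSV array containers with a sidecar metadata CSV, and
#'   a cohort manifest CSV plus ground-truth JSON are written alongside.
#' @return list with \code{patients} (list as from
#'   \code{\link{generatePatient}}) and \code{manifest} (data.frame:
#'   patient, sozSide, nChannels, nEpochs).
#' @export
generateCohort <- function(cfg, writeDir = NULL) {
  patients <- lapply(seq_len(cfg$nPatients), function(i)
    generatePatient(cfg, i))
  manifest <- data.frame(
    patient = sprintf("sub-%03d", seq_len(cfg$nPatients)),
    sozSide = cfg$sozSides,
    nChannels = vapply(patients, function(p) nrow(p$channels), 0L),
    nEpochs = cfg$nEpochs, stringsAsFactors = FALSE)
  if (!is.null(writeDir)) {
    dir.create(writeDir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(patients)) {
      pd <- file.path(writeDir, manifest$patient[i])
      dir.create(pd, showWarnings = FALSE)
      for (ei in seq_along(patients[[i]]$epochs@epochs))
        utils::write.table(patients[[i]]$epochs@epochs[[ei]]@data,
                           file.path(pd, sprintf("epoch-%02d.csv", ei)),
                           sep = ",", row.names = FALSE, col.names = FALSE)
      utils::write.csv(patients[[i]]$channels,
                       file.path(pd, "channels.csv"), row.names = FALSE)
    }
    utils::write.csv(manifest, file.path(writeDir, "manifest.csv"),
                     row.names = FALSE)
    truth <- lapply(patients, function(p)
      p$truth[c("sozSide", "gains", "artifactChannels")])
    names(truth) <- manifest$patient
    jsonlite::write_json(truth, file.path(writeDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(patients = patients, manifest = manifest)
}

#' Synthetic per-pipeline networks with planted family structure
#'
#' Generates, for each synthetic patient, one network per pipeline in
#' which edge-weight vectors share a latent factor within each of three
#' pipeline families - relative-entropy pipelines (both references),
#' CAR non-RE pipelines, and bipolar non-RE pipelines - plus independent
#' edge noise. This plants the three-family similarity structure observed
#' empirically in clinical iEEG cohorts, providing ground truth for
#' clustering-recovery tests of the similarity module.
#'
#' @param nPatients number of synthetic patients.
#' @param nContacts contacts per hemisphere montage used for node naming.
#' @param noiseSd edge-noise standard deviation relative to the unit
#'   family factor (within-family correlation ~ 1 / (1 + noiseSd^2)).
#' @param seed integer seed.
#' @return list over patients of named \code{\link{ConnectivityNetwork}}
#'   lists (48 pipelines), plus attribute \code{"families"}: the planted
#'   family id per pipeline key.
#' @export
simulatePipelineFamilies <- function(nPatients = 10, nContacts = 10,
                                     noiseSd = 0.35, seed = 1) {
  set.seed(as.integer(seed))
  specs <- pipelineSpecs()
  family <- ifelse(specs$measure == "re", "re",
                   ifelse(specs$scheme == "car", "car", "bipolar"))
  names(family) <- specs$key
  half <- ceiling(nContacts / 2)
  labels <- c(formatChannelLabel("LA", seq_len(half)),
              formatChannelLabel("RA", seq_len(nContacts - half)))
  nE <- choose(nContacts, 2)
  mkW <- function(v) {
    W <- matrix(0, nContacts, nContacts)
    W[upper.tri(W)] <- v
    W + t(W)
  }
  patients <- lapply(seq_len(nPatients), function(p) {
    factors <- list(re = stats::rnorm(nE), car = stats::rnorm(nE),
                    bipolar = stats::rnorm(nE))
    nets <- lapply(seq_len(nrow(specs)), function(i) {
      f <- factors[[family[specs$key[i]]]]
      v <- stats::pnorm((f + stats::rnorm(nE, sd = noiseSd)) /
                          sqrt(1 + noiseSd^2))
      ## bipolar pipelines live on one fewer node per electrode run; drop
      ## the last contact to exercise anchor-based edge alignment
      if (specs$scheme[i] == "bipolar") {
        W <- mkW(v)[-nContacts, -nContacts]
        connectivityNetwork(W, nodes = labels[-nContacts],
                            measure = specs$measure[i], band = specs$band[i],
                            scheme = specs$scheme[i], nWindows = 1)
      } else {
        connectivityNetwork(mkW(v), nodes = labels,
                            measure = specs$measure[i], band = specs$band[i],
                            scheme = specs$scheme[i], nWindows = 1)
      }
    })
    names(nets) <- specs$key
    nets
  })
  attr(patients, "families") <- family
  patients
}
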