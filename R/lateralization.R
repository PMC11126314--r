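#' Match contacts with symmetric contralateral counterparts
#'
#' A contact is kept iff the label formed by swapping the leading L/R of
#' its electrode name exists and is retained (e.g. LA01 matches RA01).
#' This spatial downsampling controls for anatomical differences and for
#' denser sampling near the suspected seizure onset zone.
#'
#' @param channels channel metadata \code{data.frame}.
#' @return \code{data.frame} of matched pairs with columns \code{left},
#'   \code{right}.
#' @export
matchSymmetricContacts <- function(channels) {
  ch <- channels[channels$retained, , drop = FALSE]
  lead <- substr(ch$electrode, 1, 1)
  if (!all(lead %in% c("L", "R")))
    stop("labels must start with a hemisphere letter L or R")
  mirror <- paste0(ifelse(lead == "L", "R", "L"), substring(ch$electrode, 2))
  mirrorLabel <- formatChannelLabel(mirror, ch$contact)
  have <- mirrorLabel %in% ch$label
  keep <- ch[have & lead == "L", , drop = FALSE]
  if (!nrow(keep))
    stop("patient excluded: no symmetric contact pairs across hemispheres")
  data.frame(left = keep$label,
             right = formatChannelLabel(
               paste0("R", substring(keep$electrode, 2)), keep$contact),
             stringsAsFactors = FALSE)
}

#' Mean intra-hemisphere connectivity
#'
#' Mean of edge weights among within-side nodes only (cross-hemisphere
#' edges excluded). Nodes are selected through their anchor contact: a
#' node belongs to the side if its anchor is one of that side's matched
#' contacts.
#'
#' @param net a \code{\link{ConnectivityNetwork}}.
#' @param matched matched-pair table from
#'   \code{\link{matchSymmetricContacts}}.
#' @param side \code{"L"} or \code{"R"}.
#' @return scalar mean connectivity, or \code{NA} if fewer than one
#'   within-side edge is defined.
#' @export
hemisphereConnectivity <- function(net, matched, side = c("L", "R")) {
  side <- match.arg(side)
  contacts <- if (side == "L") matched$left else matched$right
  idx <- which(net@anchors %in% contacts)
  if (length(idx) < 2) return(NA_real_)
  W <- net@weights[idx, idx, drop = FALSE]
  v <- W[upper.tri(W)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment across the family of pipelines tested
#' in a run. Wraps \code{stats::p.adjust(method = "BH")} after range
#' validation.
#'
#' @param p vector of raw p-values in [0, 1].
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Paired SOZ-vs-contralateral test for one pipeline
#'
#' Paired t-test on per-patient differences (SOZ-side minus non-SOZ-side
#' mean connectivity), with paired Cohen's d = mean(diff) / sd(diff) and
#' percent change 100 * (mean SOZ - mean non-SOZ) / mean non-SOZ.
#'
#' @param soz,nonSoz per-patient hemisphere means (equal length, >= 3
#'   complete pairs).
#' @return one-row \code{data.frame} with \code{t}, \code{df}, \code{p},
#'   \code{cohenD}, \code{percentChange}, \code{n}.
#' @export
pairedLateralizationTest <- function(soz, nonSoz) {
  ok <- is.finite(soz) & is.finite(nonSoz)
  soz <- soz[ok]; nonSoz <- nonSoz[ok]
  if (length(soz) < 3)
    stop("paired lateralization test requires >= 3 patients with values")
  d <- soz - nonSoz
  sdd <- stats::sd(d)
  if (sdd == 0) {
    warning("zero-variance differences; t and d undefined")
    return(data.frame(t = NA_real_, df = length(d) - 1, p = NA_real_,
                      cohenD = NA_real_,
                      percentChange = 100 * mean(d) / mean(nonSoz),
                      n = length(d)))
  }
  tt <- stats::t.test(soz, nonSoz, paired = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, cohenD = mean(d) / sdd,
             percentChange = 100 * (mean(soz) - mean(nonSoz)) / mean(nonSoz),
             n = length(d))
}

#' Lateralization statistics across a cohort for every pipeline
#'
#' For each pipeline, per-patient SOZ-side and non-SOZ-side mean
#' intra-hemisphere connectivity values are compared with a paired t-test;
#' p-values are Benjamini-Hochberg adjusted across the pipeline family.
#'
#' @param perPatientNets list over patients of named pipeline-network
#'   lists (as from \code{\link{runPipelineSuite}}).
#' @param channelsPerPatient list of channel metadata tables (original
#'   contacts, for symmetric matching).
#' @param sozSides character vector of per-patient SOZ sides (\code{"L"} /
#'   \code{"R"}).
#' @return \code{data.frame} with one row per pipeline: \code{pipeline},
#'   \code{t}, \code{df}, \code{p}, \code{pAdj}, \code{cohenD},
#'   \code{percentChange}, \code{n}.
#' @export
lateralizeCohort <- function(perPatientNets, channelsPerPatient, sozSides) {
  stopifnot(length(perPatientNets) == length(channelsPerPatient),
            length(perPatientNets) == length(sozSides),
            all(sozSides %in% c("L", "R")))
  keys <- names(perPatientNets[[1]])
  matchedList <- lapply(channelsPerPatient, matchSymmetricContacts)
  rows <- lapply(keys, function(key) {
    soz <- nonSoz <- rep(NA_real_, length(perPatientNets))
    for (i in seq_along(perPatientNets)) {
      net <- perPatientNets[[i]][[key]]
      if (is.null(net)) next
      lv <- hemisphereConnectivity(net, matchedList[[i]], "L")
      rv <- hemisphereConnectivity(net, matchedList[[i]], "R")
      if (sozSides[i] == "L") { soz[i] <- lv; nonSoz[i] <- rv }
      else { soz[i] <- rv; nonSoz[i] <- lv }
    }
    cbind(pipeline = key, pairedLateralizationTest(soz, nonSoz))
  })
  out <- do.call(rbind, rows)
  out$pAdj <- NA_real_
  ok <- is.finite(out$p)
  out$pAdj[ok] <- bhAdjust(out$p[ok])
  out
}
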