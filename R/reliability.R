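#' Node strength of a connectivity network
#'
#' Sum of absolute edge weights from each retained node to the other
#' retained nodes. Absolute weights make signed Pearson and
#' relative-entropy networks comparable; set \code{absolute = FALSE} for
#' raw sums.
#'
#' @param net a \code{\link{ConnectivityNetwork}}.
#' @param subset node names to retain (default all); at least 2.
#' @param absolute use |w| (default TRUE).
#' @return named numeric vector of strengths.
#' @export
nodeStrength <- function(net, subset = NULL, absolute = TRUE) {
  nodes <- net@nodes
  if (is.null(subset)) subset <- nodes
  stopifnot(all(subset %in% nodes))
  if (length(subset) < 2)
    stop("node strength requires >= 2 retained nodes")
  idx <- match(subset, nodes)
  W <- net@weights[idx, idx, drop = FALSE]
  if (absolute) W <- abs(W)
  s <- rowSums(W, na.rm = TRUE)
  names(s) <- subset
  s
}

#' Reliability of node strength under random channel removal
#'
#' Per iteration, \code{floor(fraction * n)} channels are removed
#' uniformly without replacement and node strengths of the remaining
#' channels are computed. The error variance \code{sigmaE} is the variance
#' of a channel's strength across the iterations in which that channel was
#' retained, averaged across channels; the true variance \code{sigmaT} is
#' the variance of strength across channels within an iteration, averaged
#' across iterations. Reliability R = sigmaT / (sigmaT + sigmaE) lies in
#' [0, 1]; 1 means node strengths are fully robust to subsampling.
#'
#' @param net a \code{\link{ConnectivityNetwork}}.
#' @param fraction fraction of channels removed, in (0, 1).
#' @param nIter number of random subsamples (default 1000).
#' @param seed integer seed.
#' @param exhaustive if TRUE enumerate every subset of the given size
#'   instead of sampling (feasible only for small networks); used as an
#'   exact oracle. The enumeration is the complete population of subsets,
#'   so across-iteration variances use the population denominator, making
#'   the sampled estimate converge to the exhaustive value as \code{nIter}
#'   grows.
#' @param absolute passed to \code{\link{nodeStrength}}.
#' @return list with \code{R}, \code{sigmaT}, \code{sigmaE},
#'   \code{fraction}, \code{nIter}. Degenerate networks with
#'   \code{sigmaT = sigmaE = 0} yield \code{R = NA} with a warning.
#' @export
subsampleReliability <- function(net, fraction, nIter = 1000, seed = 1,
                                 exhaustive = FALSE, absolute = TRUE) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  nodes <- net@nodes
  n <- length(nodes)
  nRemove <- floor(fraction * n)
  nKeep <- n - nRemove
  if (nKeep < 2) stop("removal would leave fewer than 2 nodes")
  keepSets <- if (exhaustive) {
    asplit(utils::combn(n, nKeep), 2)
  } else {
    set.seed(as.integer(seed))
    lapply(seq_len(nIter), function(i) sort(sample(n, nKeep)))
  }
  strengths <- matrix(NA_real_, length(keepSets), n,
                      dimnames = list(NULL, nodes))
  for (i in seq_along(keepSets)) {
    keep <- nodes[keepSets[[i]]]
    strengths[i, keep] <- nodeStrength(net, keep, absolute = absolute)
  }
  perIterVar <- apply(strengths, 1, function(v) stats::var(v[is.finite(v)]))
  sigmaT <- mean(perIterVar, na.rm = TRUE)
  nRet <- colSums(is.finite(strengths))
  usable <- nRet >= 2
  if (any(!usable))
    message(sum(!usable), " contact(s) retained in < 2 iterations excluded ",
            "from error-variance averaging")
  perChanVar <- apply(strengths[, usable, drop = FALSE], 2, function(v) {
    v <- v[is.finite(v)]
    va <- stats::var(v)
    if (exhaustive) va * (length(v) - 1) / length(v) else va
  })
  sigmaE <- mean(perChanVar)
  R <- if (sigmaT + sigmaE == 0) {
    warning("sigmaT and sigmaE both zero; reliability undefined")
    NA_real_
  } else sigmaT / (sigmaT + sigmaE)
  list(R = R, sigmaT = sigmaT, sigmaE = sigmaE, fraction = fraction,
       nIter = length(keepSets))
}

#' Reliability curve over the canonical removal fractions
#'
#' @param net a \code{\link{ConnectivityNetwork}}.
#' @param fractions removal fractions (default 0.2, 0.4, 0.6, 0.8).
#' @param ... passed to \code{\link{subsampleReliability}}.
#' @return \code{data.frame} with columns \code{fraction}, \code{R},
#'   \code{sigmaT}, \code{sigmaE}.
#' @export
reliabilityCurve <- function(net, fractions = c(0.2, 0.4, 0.6, 0.8), ...) {
  rows <- lapply(fractions, function(f) {
    r <- subsampleReliability(net, f, ...)
    data.frame(fraction = f, R = r$R, sigmaT = r$sigmaT, sigmaE = r$sigmaE)
  })
  do.call(rbind, rows)
}

## Dunn-Sidak post hoc for a Friedman design: z from mean-rank differences,
## Sidak-corrected over all group pairs
.dunnSidak <- function(X) {
  n <- nrow(X); k <- ncol(X)
  ranks <- t(apply(X, 1, rank))
  mr <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = colnames(X)[pairs[1, ]],
                    group2 = colnames(X)[pairs[2, ]],
                    z = (mr[pairs[1, ]] - mr[pairs[2, ]]) / se)
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$pAdj <- pmin(1, 1 - (1 - out$p)^m)
  out$significant <- out$pAdj < 0.05
  out
}

#' Compare reliability across pipeline groupings
#'
#' Reliability values are arranged as a patients x groups matrix by
#' averaging pipelines within the grouping: two reference schemes are
#' compared with a paired Wilcoxon signed-rank test; connectivity-measure
#' or frequency-band groupings use a Friedman test with Dunn-Sidak post
#' hoc pairwise comparisons. Patients with incomplete rows are dropped.
#'
#' @param values numeric matrix, patients x groups, with column names.
#' @param grouping \code{"reference"} (2 columns, Wilcoxon) or
#'   \code{"measure"}/\code{"band"} (Friedman + post hoc).
#' @return list with the omnibus \code{statistic}, \code{p}, the test
#'   name, and for Friedman designs a \code{posthoc} data.frame.
#' @export
compareReliability <- function(values, grouping = c("measure", "band",
                                                    "reference")) {
  grouping <- match.arg(grouping)
  complete <- stats::complete.cases(values)
  if (any(!complete))
    message(sum(!complete), " patient(s) with incomplete rows dropped")
  X <- as.matrix(values[complete, , drop = FALSE])
  if (grouping == "reference") {
    stopifnot(ncol(X) == 2)
    wt <- stats::wilcox.test(X[, 1], X[, 2], paired = TRUE, exact = FALSE)
    return(list(test = "wilcoxon_signed_rank",
                statistic = unname(wt$statistic), p = wt$p.value))
  }
  ft <- stats::friedman.test(X)
  list(test = "friedman", statistic = unname(ft$statistic),
       df = unname(ft$parameter), p = ft$p.value, posthoc = .dunnSidak(X))
}
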