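#' Extract the canonical edge-weight vector of a network
#'
#' Returns the upper-triangle edge weights in canonical node order. Nodes
#' are identified by their anchor contact (for bipolar montages the
#' lower-numbered parent), so CAR and bipolar networks align on the common
#' contact set; edges are named \code{"A|B"} with anchors sorted. Pairwise
#' comparisons should intersect the names of two such vectors, dropping
#' unmatched edges symmetrically.
#'
#' @param net a \code{\link{ConnectivityNetwork}}.
#' @return named numeric vector of edge weights.
#' @export
edgeVector <- function(net) {
  anchors <- net@anchors
  if (length(anchors) < 2)
    stop("network has fewer than 2 nodes; no comparable edges")
  ord <- order(anchors)
  W <- net@weights[ord, ord, drop = FALSE]
  a <- anchors[ord]
  idx <- which(upper.tri(W), arr.ind = TRUE)
  v <- W[idx]
  names(v) <- paste(a[idx[, 1]], a[idx[, 2]], sep = "|")
  v
}

#' Edge-wise similarity between pre-processing pipelines
#'
#' For each patient, the Pearson correlation between every pair of
#' pipelines' aligned edge vectors is computed (edges matched by anchor
#' pair; unmatched edges dropped from both sides); patient matrices are
#' then averaged element-wise into the group similarity matrix. A pair
#' with a constant edge vector has undefined correlation for that patient
#' and is excluded from the average.
#'
#' @param perPatientNets list over patients; each element a named list of
#'   \code{\link{ConnectivityNetwork}} objects (one per pipeline, shared
#'   names).
#' @param minEdges minimum number of aligned edges required per pair.
#' @return list with \code{S} (group similarity matrix), \code{perPatient}
#'   (list of per-patient matrices).
#' @export
pipelineSimilarity <- function(perPatientNets, minEdges = 3) {
  keys <- names(perPatientNets[[1]])
  perPatient <- lapply(perPatientNets, function(nets) {
    vecs <- lapply(nets[keys], edgeVector)
    np <- length(keys)
    S <- matrix(NA_real_, np, np, dimnames = list(keys, keys))
    diag(S) <- 1
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      common <- intersect(names(vecs[[i]]), names(vecs[[j]]))
      if (length(common) < minEdges)
        stop(sprintf("pipelines %s and %s share only %d aligned edges",
                     keys[i], keys[j], length(common)))
      a <- vecs[[i]][common]; b <- vecs[[j]][common]
      ok <- is.finite(a) & is.finite(b)
      r <- suppressWarnings(stats::cor(a[ok], b[ok]))
      S[i, j] <- S[j, i] <- r
    }
    S
  })
  arr <- simplify2array(perPatient)
  S <- apply(arr, c(1, 2), function(v) mean(v[is.finite(v)]))
  diag(S) <- 1
  list(S = S, perPatient = perPatient)
}

#' Hierarchical clustering of pipelines
#'
#' Agglomerative clustering with average linkage on the distance
#' D = 1 - S, cut at \code{k} clusters.
#'
#' @param S symmetric similarity matrix (unit diagonal).
#' @param k number of clusters (default 3, separating the relative-entropy
#'   family from the two reference families).
#' @return list with \code{labels} (named cluster ids), \code{tree}
#'   (the \code{hclust} object) and \code{k}.
#' @export
hierarchicalClusters <- function(S, k = 3) {
  n <- nrow(S)
  stopifnot(k >= 1)
  if (k > n) stop("k cannot exceed the number of pipelines")
  D <- stats::as.dist(1 - S)
  tree <- stats::hclust(D, method = "average")
  labels <- stats::cutree(tree, k = k)
  names(labels) <- rownames(S)
  list(labels = labels, tree = tree, k = k)
}

## cluster-wise maximum Jaccard overlap of a reference partition against
## another partition of the same items
.clusterJaccard <- function(refLabels, bootLabels) {
  vapply(sort(unique(refLabels)), function(cl) {
    a <- names(refLabels)[refLabels == cl]
    max(vapply(unique(bootLabels), function(bl) {
      b <- names(bootLabels)[bootLabels == bl]
      length(intersect(a, b)) / length(union(a, b))
    }, 0))
  }, 0)
}

#' Bootstrap stability of pipeline clusters
#'
#' The reference clustering is computed from the full-cohort mean
#' similarity matrix. For each bootstrap resample, patients are resampled
#' with replacement, the mean similarity matrix recomputed and
#' reclustered, and each reference cluster scored by its maximum Jaccard
#' overlap with the resample clusters. Stability is the mean Jaccard over
#' resamples (per cluster and overall). With \code{selectK = TRUE} the
#' procedure is repeated with \code{nSelect} resamples for each candidate
#' k and the k maximizing mean stability is reported.
#'
#' @param perPatientS list of per-patient similarity matrices.
#' @param k number of clusters for the stability assessment.
#' @param nBoot bootstrap resamples for stability (default 1000).
#' @param nSelect resamples per candidate k during k selection (default
#'   20).
#' @param kCandidates candidate cluster counts for selection.
#' @param selectK also run the k-selection mode.
#' @param seed integer seed.
#' @return list with \code{labels}, \code{stability} (per cluster),
#'   \code{meanStability}, and optionally \code{kSelection}.
#' @export
bootstrapStability <- function(perPatientS, k = 3, nBoot = 1000,
                               nSelect = 20, kCandidates = 2:6,
                               selectK = FALSE, seed = 1) {
  stopifnot(length(perPatientS) >= 2, nBoot >= 2)
  set.seed(as.integer(seed))
  meanS <- function(lst) {
    arr <- simplify2array(lst)
    M <- apply(arr, c(1, 2), function(v) mean(v[is.finite(v)]))
    diag(M) <- 1
    M
  }
  full <- meanS(perPatientS)
  stabilityFor <- function(kk, nRes) {
    ref <- hierarchicalClusters(full, kk)$labels
    jac <- matrix(0, nRes, kk)
    for (b in seq_len(nRes)) {
      idx <- sample(length(perPatientS), replace = TRUE)
      Sb <- meanS(perPatientS[idx])
      bl <- hierarchicalClusters(Sb, kk)$labels
      jac[b, ] <- .clusterJaccard(ref, bl)
    }
    list(ref = ref, perCluster = colMeans(jac), mean = mean(jac))
  }
  out <- stabilityFor(k, nBoot)
  result <- list(k = k, labels = out$ref, stability = out$perCluster,
                 meanStability = out$mean)
  if (selectK) {
    sel <- vapply(kCandidates, function(kk) stabilityFor(kk, nSelect)$mean, 0)
    names(sel) <- kCandidates
    result$kSelection <- list(meanStability = sel,
                              kBest = kCandidates[which.max(sel)])
  }
  result
}

## ---- compact exact t-SNE on a precomputed distance matrix ----

## perplexity calibration: binary search the Gaussian bandwidth per point
.tsneP <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

#' Embed the pipeline similarity matrix in two dimensions with t-SNE
#'
#' Exact t-distributed stochastic neighbour embedding on the distance
#' 1 - S (gradient descent with momentum and early exaggeration),
#' reproducible for a fixed seed.
#'
#' @param S similarity matrix.
#' @param perplexity t-SNE perplexity (must satisfy
#'   \code{3 * perplexity < n - 1}).
#' @param nIter gradient-descent iterations.
#' @param seed integer seed.
#' @return n x 2 matrix of embedding coordinates (rownames from S).
#' @export
embed2d <- function(S, perplexity = 10, nIter = 500, seed = 1) {
  n <- nrow(S)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity too large for the number of items: need 3*perplexity < n-1")
  D <- 1 - S
  diag(D) <- 0
  P <- .tsneP(D^2, perplexity)
  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 20
  for (it in seq_len(nIter)) {
    Pe <- if (it <= 50) P * 4 else P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- pmax(0.01, ifelse(sign(grad) != sign(G), gains + 0.2,
                               gains * 0.8))
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(S)
  Y
}
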