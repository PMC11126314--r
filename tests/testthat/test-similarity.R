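test_that("edge vectors have C(n,2) entries and are permutation-invariant", {
  W <- matrix(c(NA, 1, 2, 1, NA, 3, 2, 3, NA), 3)
  net <- toyNet(W, labels = c("LA01", "LA02", "LA03"))
  v <- edgeVector(net)
  expect_length(v, 3)
  expect_named(v, c("LA01|LA02", "LA01|LA03", "LA02|LA03"))

  # shuffled node order yields the identical canonical vector
  perm <- c(3, 1, 2)
  net2 <- connectivityNetwork(W[perm, perm],
                              nodes = c("LA03", "LA01", "LA02"),
                              measure = "re", scheme = "car")
  expect_identical(edgeVector(net2), v)
})

test_that("bipolar nodes align to anchor contacts for cross-montage comparison", {
  carNet <- toyNet(matrix(runif(16), 4, 4) * 0 + 0.5,
                   labels = formatChannelLabel("LA", 1:4))
  bipNet <- connectivityNetwork(matrix(0.25, 3, 3),
                                nodes = c("LA01-LA02", "LA02-LA03", "LA03-LA04"),
                                measure = "coh", scheme = "bipolar",
                                anchors = c("LA01", "LA02", "LA03"))
  a <- edgeVector(carNet); b <- edgeVector(bipNet)
  common <- intersect(names(a), names(b))
  expect_length(common, 3)   # C(3,2) aligned edges on the shared anchors
})

test_that("pipeline similarity is 1 on self and affine copies, and matches a hand oracle", {
  set.seed(30)
  labels <- formatChannelLabel("LA", 1:4)
  mkNet <- function(v) {
    W <- matrix(0, 4, 4); W[upper.tri(W)] <- v; W <- W + t(W)
    toyNet(W, measure = "re", labels = labels)
  }
  v1 <- runif(6); v2 <- runif(6); v3 <- runif(6)
  nets <- list(a = mkNet(v1), b = mkNet(2 * v1 + 3), c = mkNet(v2))
  out <- pipelineSimilarity(list(p1 = nets))
  expect_equal(diag(out$S), c(a = 1, b = 1, c = 1))
  expect_equal(out$S["a", "b"], 1)                    # affine invariance
  expect_equal(out$S["a", "c"], cor(v1, v2))          # direct formula

  # averaging across patients is the plain mean of per-patient r
  nets2 <- list(a = mkNet(v2), b = mkNet(v3), c = mkNet(v1))
  out2 <- pipelineSimilarity(list(p1 = nets, p2 = nets2))
  expect_equal(out2$S["a", "c"],
               mean(c(cor(v1, v2), cor(v2, v1))))
})

test_that("average-linkage clustering recovers planted partitions", {
  S2 <- plantedS(c(5, 7))
  cl2 <- hierarchicalClusters(S2, k = 2)
  expect_equal(length(unique(cl2$labels[1:5])), 1)
  expect_equal(length(unique(cl2$labels[6:12])), 1)
  expect_false(cl2$labels[1] == cl2$labels[6])

  S3 <- plantedS(c(4, 5, 6), noise = 0.03, seed = 2)
  cl3 <- hierarchicalClusters(S3, k = 3)
  truth <- rep(1:3, c(4, 5, 6))
  expect_equal(length(unique(paste(cl3$labels, truth))), 3)  # exact recovery

  expect_equal(length(unique(hierarchicalClusters(S3, k = 15)$labels)), 15)
  expect_error(hierarchicalClusters(S3, k = 16), "exceed")
})

test_that("clustering is invariant to item order", {
  S <- plantedS(c(4, 4, 4), noise = 0.05, seed = 3)
  cl <- hierarchicalClusters(S, k = 3)$labels
  set.seed(4)
  perm <- sample(12)
  clP <- hierarchicalClusters(S[perm, perm], k = 3)$labels
  # same partition up to label renaming
  expect_equal(length(unique(paste(cl[perm], clP))), 3)
})

test_that("bootstrap stability is 1 for identical structured patients and low for noise", {
  S <- plantedS(c(4, 5, 7))
  res <- bootstrapStability(rep(list(S), 6), k = 3, nBoot = 50, seed = 5)
  expect_equal(res$meanStability, 1)
  expect_equal(unname(res$stability), c(1, 1, 1))

  set.seed(6)
  noiseS <- replicate(8, {
    E <- matrix(rnorm(144, sd = 0.3), 12)
    S0 <- (E + t(E)) / 2; diag(S0) <- 1
    dimnames(S0) <- list(paste0("p", 1:12), paste0("p", 1:12))
    S0
  }, simplify = FALSE)
  resN <- bootstrapStability(noiseS, k = 3, nBoot = 60, seed = 7)
  expect_lt(resN$meanStability, 0.6)

  resA <- bootstrapStability(noiseS, k = 3, nBoot = 40, seed = 8)
  resB <- bootstrapStability(noiseS, k = 3, nBoot = 40, seed = 8)
  expect_identical(resA, resB)
  expect_error(bootstrapStability(noiseS, k = 3, nBoot = 1), "nBoot")
})

test_that("k selection prefers the planted cluster count", {
  pats <- lapply(1:6, function(i) plantedS(c(5, 5, 6), noise = 0.05, seed = i))
  res <- bootstrapStability(pats, k = 3, nBoot = 20, nSelect = 15,
                            kCandidates = 2:5, selectK = TRUE, seed = 9)
  expect_true(res$kSelection$kBest %in% c(2, 3))
  expect_gt(res$kSelection$meanStability["3"],
            res$kSelection$meanStability["5"])
})

test_that("t-SNE separates planted blocks, is seed-stable and maps duplicates together", {
  S <- plantedS(c(5, 5, 6), noise = 0.02, seed = 10)
  lab <- rep(1:3, c(5, 5, 6))
  seps <- vapply(1:5, function(s) {
    Y <- embed2d(S, perplexity = 3, nIter = 300, seed = s)
    D <- as.matrix(dist(Y))
    same <- outer(lab, lab, `==`) & upper.tri(D)
    diff <- outer(lab, lab, `!=`) & upper.tri(D)
    mean(D[same]) < mean(D[diff])
  }, TRUE)
  expect_gte(mean(seps), 0.8)

  expect_identical(embed2d(S, perplexity = 3, nIter = 100, seed = 3),
                   embed2d(S, perplexity = 3, nIter = 100, seed = 3))

  Sdup <- S
  Sdup[2, ] <- Sdup[1, ]; Sdup[, 2] <- Sdup[, 1]
  Sdup[1, 2] <- Sdup[2, 1] <- 1; diag(Sdup) <- 1
  Y <- embed2d(Sdup, perplexity = 3, nIter = 400, seed = 11)
  D <- as.matrix(dist(Y))
  expect_lt(D[1, 2], 0.05 * max(D))

  expect_error(embed2d(S, perplexity = 10), "perplexity")
})

test_that("planted pipeline families are recovered by k = 3 clustering", {
  pats <- simulatePipelineFamilies(nPatients = 6, seed = 12)
  fam <- attr(pats, "families")
  sim <- pipelineSimilarity(pats)
  cl <- hierarchicalClusters(sim$S, k = 3)$labels
  # partition must coincide with the planted family assignment
  expect_equal(length(unique(paste(cl, fam[names(cl)]))), 3)
  # within-family similarity clearly exceeds between-family similarity
  sameFam <- outer(fam[rownames(sim$S)], fam[colnames(sim$S)], `==`)
  ut <- upper.tri(sim$S)
  expect_gt(mean(sim$S[sameFam & ut]), mean(sim$S[!sameFam & ut]) + 0.3)
})
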