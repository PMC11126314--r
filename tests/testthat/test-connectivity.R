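test_that("windowing yields floor(n / window) windows and rejects short epochs", {
  rec <- noiseRec(2, fs = 512, durS = 120)
  expect_length(windowSignal(rec), 60)
  expect_equal(ncol(windowSignal(rec)[[1]]), 1024)
  rec5 <- noiseRec(2, fs = 512, durS = 5)
  expect_length(windowSignal(rec5), 2)
  expect_error(windowSignal(noiseRec(2, fs = 512, durS = 1)), "shorter")
})

test_that("Pearson networks match identities and the per-window oracle", {
  set.seed(10)
  x <- rnorm(600)
  rec <- recFromRows(list(x, x, -x), fs = 100)
  net <- pearsonNetwork(rec, windowS = 2)
  W <- edgeWeights(net)
  expect_equal(W[1, 2], 1)
  expect_equal(W[1, 3], -1)
  sq <- edgeWeights(pearsonNetwork(rec, windowS = 2, squared = TRUE))
  expect_equal(sq[1, 3], 1)

  r3 <- noiseRec(3, fs = 100, durS = 6, seed = 11)
  got <- edgeWeights(pearsonNetwork(r3, windowS = 2))
  expect_equal(unname(got), oraclePearson(signalData(r3), 100), tolerance = 1e-12)
})

test_that("cross-correlation recovers shifts inside the lag range only", {
  fs <- 512
  set.seed(12)
  x <- rnorm(4 * fs)
  d50 <- round(0.05 * fs); d300 <- round(0.3 * fs)
  shift <- function(v, d) c(rep(0, d), v[1:(length(v) - d)])
  rec <- recFromRows(list(x, shift(x, d50), shift(x, d300)), fs)
  W <- edgeWeights(xcorrNetwork(rec, windowS = 2, maxLagMs = 200))
  expect_gte(W[1, 2], 0.95)     # 50 ms shift recovered
  expect_lt(W[1, 3], 0.2)       # 300 ms shift outside the 200 ms lag range
  expect_equal(edgeWeights(xcorrNetwork(recFromRows(list(x, x), fs)))[1, 2], 1)
})

test_that("cross-correlation equals the brute-force lag-scan oracle", {
  fs <- 256
  r3 <- noiseRec(3, fs = fs, durS = 2, seed = 13)  # a single 2-s window
  W <- edgeWeights(xcorrNetwork(r3, windowS = 2, maxLagMs = 200))
  X <- signalData(r3)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(W[i, j], oracleXcorrPair(X[i, ], X[j, ], fs, 200),
                 tolerance = 1e-9)
  expect_error(xcorrNetwork(r3, windowS = 2, maxLagMs = 2000), "smaller")
})

test_that("coherence is 1 for identical signals and band-selective for shared rhythms", {
  fs <- 512
  set.seed(14)
  x <- rnorm(8 * fs)
  rec <- recFromRows(list(x, x), fs)
  for (b in c("delta", "alpha", "gamma"))
    expect_equal(edgeWeights(coherenceNetwork(rec, b))[1, 2], 1,
                 tolerance = 1e-9)

  shared <- sin(2 * pi * 10 * seq(0, 8 - 1 / fs, by = 1 / fs))
  rec2 <- recFromRows(list(shared + 3 * rnorm(8 * fs),
                           shared + 3 * rnorm(8 * fs)), fs)
  alpha <- edgeWeights(coherenceNetwork(rec2, "alpha"))[1, 2]
  gamma <- edgeWeights(coherenceNetwork(rec2, "gamma"))[1, 2]
  expect_gt(alpha, gamma)
})

test_that("coherence matches the FFT oracle and shows the 1/K null bias", {
  fs <- 256
  r3 <- noiseRec(3, fs = fs, durS = 12, seed = 15)
  W <- edgeWeights(coherenceNetwork(r3, "broadband"))
  X <- signalData(r3)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(W[i, j],
                 oracleCoherencePair(X[i, ], X[j, ], fs, 2, 0.5, fs / 2),
                 tolerance = 1e-9)

  # zero-coherence bias ~ 1/K for K averaged segments (Monte-Carlo check)
  set.seed(16)
  vals <- replicate(12, {
    r <- noiseRec(2, fs = 128, durS = 120, seed = sample.int(1e6, 1))
    edgeWeights(coherenceNetwork(r, "broadband"))[1, 2]
  })
  expect_lt(abs(mean(vals) - 1 / 60), 3 * sd(vals) / sqrt(length(vals)))

  expect_error(coherenceNetwork(noiseRec(2, fs = 256, durS = 2), "alpha"),
               ">= 2 windows")
})

test_that("PLV is 1 for constant phase lags and small for independent noise", {
  fs <- 512
  rec <- sineRec(c(10, 10), fs = fs, durS = 8, phases = c(0, pi / 2))
  expect_gte(edgeWeights(plvNetwork(rec, "alpha"))[1, 2], 0.99)
  set.seed(17)
  x <- rnorm(8 * fs)
  expect_equal(edgeWeights(plvNetwork(recFromRows(list(x, x), fs),
                                      "alpha"))[1, 2], 1, tolerance = 1e-9)
  noise <- noiseRec(2, fs = 256, durS = 32, seed = 18)
  # the null PLV level is set by the number of independent phase samples
  # per window; longer windows push it down
  short <- edgeWeights(plvNetwork(noise, "alpha", windowS = 4))[1, 2]
  expect_lt(short, 0.25)
  long <- edgeWeights(plvNetwork(noise, "alpha", windowS = 16))[1, 2]
  expect_lt(long, short)
})

test_that("relative entropy matches the histogram-KL oracle and the max rule", {
  fs <- 200
  set.seed(19)
  # order invariance: permutation leaves amplitude distribution unchanged
  x <- rnorm(fs * 2)
  recPerm <- recFromRows(list(x, sample(x)), fs)
  # broadband at fs = 200 clips the upper band edge (warning checked in
  # the signals tests)
  Wp <- edgeWeights(suppressWarnings(
    relativeEntropyNetwork(recPerm, "broadband", windowS = 2)))
  # order invariance is exact on raw amplitudes (oracle below); after the
  # broadband band-pass it holds to the filter's residual
  expect_lt(Wp[1, 2], 0.01)
  expect_equal(edgeWeights(suppressWarnings(relativeEntropyNetwork(
    recFromRows(list(x, x), fs), "broadband")))[1, 2], 0)

  # against the oracle on raw (unfiltered) draws, single window
  x <- rnorm(1e5); y <- rnorm(1e5, sd = 2)
  kl <- oracleKL(x, y, 10)
  got <- ieegfc:::.klPair(x, y, 10)
  expect_equal(got, max(kl), tolerance = 1e-12)
  expect_gte(got, kl["pq"])
  expect_gte(got, kl["qp"])
})

test_that("RE positivity transforms behave as documented", {
  W <- matrix(c(NA, 0, 1, 0, NA, 2, 1, 2, NA), 3)
  net <- toyNet(W, measure = "re")
  inv <- edgeWeights(transformRE(net, "inverse_one_plus"))
  expect_equal(inv[1, 2], 1)
  expect_equal(inv[1, 3], 0.5)
  expect_equal(inv[2, 3], 1 / 3)
  expect_equal(edgeWeights(transformRE(net, "abs")), edgeWeights(net))
  # monotone order reversal on random RE values
  set.seed(20)
  v <- runif(10, 0, 5)
  tv <- 1 / (1 + v)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(sign(v[i] - v[j]), -sign(tv[i] - tv[j]))
  expect_error(transformRE(toyNet(W / 2, measure = "coh"), "abs"),
               "relative-entropy")
})

test_that("the suite enumerates 48 pipelines: 21 banded + 3 time-domain per reference", {
  specs <- pipelineSpecs()
  expect_equal(nrow(specs), 48)
  expect_equal(length(unique(sub("^(car|bipolar)-", "", specs$key))), 24)
  for (s in c("car", "bipolar")) {
    sub <- specs[specs$scheme == s, ]
    expect_equal(sum(is.na(sub$band)), 3)
    expect_equal(sum(!is.na(sub$band)), 21)
  }
  es <- noiseEpochs(nCh = 4, fs = 256, epochS = 6, nEpochs = 2, seed = 21)
  nets <- suppressWarnings(runPipelineSuite(es))
  expect_length(nets, 48)
  expect_setequal(names(nets), specs$key)
  nets2 <- suppressWarnings(runPipelineSuite(es))
  expect_identical(lapply(nets, edgeWeights), lapply(nets2, edgeWeights))
})

test_that("suite values equal the mean of independently computed per-epoch values", {
  es <- noiseEpochs(nCh = 4, fs = 256, epochS = 6, nEpochs = 3, seed = 22)
  nets <- suppressWarnings(runPipelineSuite(es, schemes = "car"))
  perEpoch <- lapply(epochs(es), function(ep) {
    r <- applyReference(ep, "car")
    list(pearson = edgeWeights(pearsonNetwork(r)),
         replv = edgeWeights(plvNetwork(r, "beta")),
         re = edgeWeights(relativeEntropyNetwork(r, "beta")))
  })
  avg <- function(f) Reduce(`+`, lapply(perEpoch, `[[`, f)) / length(perEpoch)
  expect_equal(edgeWeights(nets[["car-pearson"]]), avg("pearson"),
               tolerance = 1e-12)
  expect_equal(edgeWeights(nets[["car-plv-beta"]]), avg("replv"),
               tolerance = 1e-12)
  expect_equal(edgeWeights(nets[["car-re-beta"]]), avg("re"),
               tolerance = 1e-12)
})

test_that("symmetry, range and scale invariance hold on random inputs", {
  set.seed(23)
  for (rep in 1:6) {
    rec <- noiseRec(3, fs = 128, durS = 4, seed = 100 + rep)
    nets <- list(pearsonNetwork(rec), pearsonNetwork(rec, squared = TRUE),
                 xcorrNetwork(rec), coherenceNetwork(rec, "alpha"),
                 plvNetwork(rec, "alpha"),
                 relativeEntropyNetwork(rec, "alpha"))
    for (n in nets) {
      W <- edgeWeights(n)
      expect_identical(W, t(W))
      v <- W[upper.tri(W)]
      rng <- if (n@measure == "pearson") c(-1, 1) else
        if (n@measure == "re") c(0, Inf) else c(0, 1)
      expect_true(all(v >= rng[1] - 1e-9 & v <= rng[2] + 1e-9))
    }
    # positive rescaling of channels leaves pearson/coh/plv unchanged
    sc <- rec; sc@data <- diag(c(2, 0.5, 7)) %*% rec@data
    expect_equal(edgeWeights(pearsonNetwork(sc)),
                 edgeWeights(pearsonNetwork(rec)), tolerance = 1e-9)
    expect_equal(edgeWeights(coherenceNetwork(sc, "alpha")),
                 edgeWeights(coherenceNetwork(rec, "alpha")),
                 tolerance = 1e-9)
    expect_equal(edgeWeights(plvNetwork(sc, "alpha")),
                 edgeWeights(plvNetwork(rec, "alpha")), tolerance = 1e-9)
  }
})
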