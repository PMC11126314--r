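test_that("channel labels parse into electrode prefix and contact index", {
  p <- parseChannelLabel(c("LA01", "LA1", "RGRID12", "LB-03", "ra 7"))
  expect_equal(p$electrode, c("LA", "LA", "RGRID", "LB", "ra"))
  expect_equal(p$contact, c(1L, 1L, 12L, 3L, 7L))
  expect_error(parseChannelLabel("EKG"), "unparseable")
})

test_that("parse -> format -> parse round-trips on generated labels", {
  set.seed(42)
  electrodes <- replicate(50, paste(sample(LETTERS, sample(1:4, 1),
                                           replace = TRUE), collapse = ""))
  contacts <- sample(1:24, 50, replace = TRUE)
  labels <- formatChannelLabel(electrodes, contacts)
  p <- parseChannelLabel(labels)
  expect_equal(p$electrode, electrodes)
  expect_equal(p$contact, contacts)
  # idempotence of reserialization
  expect_equal(formatChannelLabel(p$electrode, p$contact), labels)
})

test_that("CSF contacts are screened out of the retained set", {
  info <- makeChannelInfo(c("LA01", "LA02", "LA03"),
                          tissue = c("grey", "csf", "white"))
  expect_equal(info$retained, c(TRUE, FALSE, TRUE))
  expect_equal(info$hemisphere, c("L", "L", "L"))
})

test_that("notch filter suppresses the line frequency and spares the passband", {
  # RMS over the central half avoids the forward-backward edge transients
  mid <- (512 * 2):(512 * 6)
  rms <- function(v) sqrt(mean(v[mid]^2))
  rec <- sineRec(c(60, 10), fs = 512, durS = 8)
  out <- notchFilter(rec, 60)
  inRms <- apply(signalData(rec), 1, rms)
  outRms <- apply(signalData(out), 1, rms)
  expect_lt(outRms[1] / inRms[1], 0.05)          # 60 Hz removed
  expect_lt(abs(outRms[2] / inRms[2] - 1), 0.05) # 10 Hz preserved
  z <- rec; z@data[] <- 0
  expect_equal(signalData(notchFilter(z, 60))
               , z@data)
  expect_error(notchFilter(sineRec(10, fs = 100), freqHz = 60), "Nyquist")
})

test_that("bandpass filter passes in-band and rejects out-of-band sinusoids", {
  rms <- function(v) sqrt(mean(v^2))
  rec <- sineRec(6, fs = 512, durS = 8)
  theta <- bandpassFilter(rec, 4, 8)
  expect_lt(abs(rms(signalData(theta)) / rms(signalData(rec)) - 1), 0.10)
  gamma <- bandpassFilter(rec, 30, 80)
  expect_lt(rms(signalData(gamma)) / rms(signalData(rec)), 0.05)
})

test_that("band upper edge clips to 0.9 x Nyquist with a warning", {
  rec <- noiseRec(1, fs = 256, durS = 4)
  expect_warning(bandpassFilter(rec, 0.5, 250), "115.2")
  expect_error(bandpassFilter(rec, 200, 250), "infeasible")
})

test_that("filters are linear within numerical tolerance", {
  x <- noiseRec(1, fs = 512, durS = 2, seed = 1)
  y <- noiseRec(1, fs = 512, durS = 2, seed = 2)
  a <- 2.5; b <- -1.3
  mix <- x; mix@data <- a * x@data + b * y@data
  for (f in list(function(r) notchFilter(r, 60),
                 function(r) bandpassFilter(r, 4, 8))) {
    lhs <- signalData(f(mix))
    rhs <- a * signalData(f(x)) + b * signalData(f(y))
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
  }
})

test_that("epoch selection is seed-reproducible, disjoint and in-window", {
  rec <- noiseRec(2, fs = 64, durS = 7200)   # 2 h starting at 13:00
  es1 <- selectEpochs(rec, nEpochs = 5, epochS = 120, seed = 7)
  es2 <- selectEpochs(rec, nEpochs = 5, epochS = 120, seed = 7)
  expect_identical(lapply(epochs(es1), signalData),
                   lapply(epochs(es2), signalData))
  starts <- vapply(epochs(es1), function(e)
    as.numeric(e@epochStart - rec@epochStart, units = "secs"), 0)
  expect_true(all(diff(sort(starts)) >= 120))          # disjoint
  expect_true(all(starts >= 0 & starts + 120 <= 7200)) # inside window
  # different seeds give different placements nearly always
  diffs <- vapply(1:30, function(s) {
    a <- selectEpochs(rec, seed = s)
    b <- selectEpochs(rec, seed = s + 1000)
    !identical(vapply(epochs(a), function(e) e@epochStart, Sys.time()),
               vapply(epochs(b), function(e) e@epochStart, Sys.time()))
  }, TRUE)
  expect_gte(mean(diffs), 0.97)
})

test_that("epoch selection fails when the window cannot hold the epochs", {
  rec <- noiseRec(1, fs = 64, durS = 9 * 60)
  expect_error(selectEpochs(rec, nEpochs = 5, epochS = 120, seed = 1),
               "insufficient")
})

test_that("artifact rejection fires on amplitude bursts and line noise", {
  fs <- 256; durS <- 8
  t <- seq(0, durS - 1 / fs, by = 1 / fs)
  set.seed(5)
  clean <- rnorm(length(t), sd = 30)
  bursty <- rnorm(length(t), sd = 30)
  idx <- sample(length(t), round(0.05 * length(t)))
  bursty[idx] <- 5000 * sign(rnorm(length(idx)))
  mains <- 100 * sin(2 * pi * 60 * t)
  rec <- recFromRows(list(clean, bursty, mains), fs,
                     labels = c("LA01", "LA02", "LA03"))
  es <- rejectArtifactChannels(epochSet(list(rec)), ampThreshUv = 500,
                               lineRatioThresh = 0.5)
  expect_equal(channelInfo(es)$retained, c(TRUE, FALSE, FALSE))
  rep <- attr(es, "rejection")
  expect_true(rep$rejected_amplitude[2])
  expect_true(rep$rejected_line[3])
  expect_gt(rep$line_ratio[3], 0.9)   # pure sine: nearly all power at 60 Hz
})

test_that("artifact rejection is monotone in the amplitude threshold", {
  es <- noiseEpochs(nCh = 6, seed = 8)
  # inject graded bursts so thresholds bite differently
  for (i in 1:6) es@epochs[[1]]@data[i, 1:200] <- i * 150
  rejAt <- function(th) !channelInfo(suppressWarnings(
    rejectArtifactChannels(es, ampThreshUv = th, lineRatioThresh = 1e6)
  ))$retained
  prev <- rejAt(1000)
  for (th in c(700, 500, 300, 100)) {
    cur <- rejAt(th)
    expect_true(all(cur[prev]))   # lowering threshold never un-rejects
    prev <- cur
  }
})

test_that("CSV array container round-trips through the reader", {
  dir <- withr::local_tempdir()
  X <- matrix(round(rnorm(64), 4), 4)
  write.table(X, file.path(dir, "d.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE)
  meta <- data.frame(label = c("LA01", "LA02", "RA01", "RA02"),
                     hemisphere = c("L", "L", "R", "R"),
                     tissue = c("grey", "white", "grey", "csf"))
  write.csv(meta, file.path(dir, "m.csv"), row.names = FALSE)
  rec <- readRecordingCSV(file.path(dir, "d.csv"), file.path(dir, "m.csv"),
                          fs = 128)
  expect_equal(unname(signalData(rec)), unname(X))
  expect_equal(referenceScheme(rec), "machine")
  expect_equal(channelInfo(rec)$retained, c(TRUE, TRUE, TRUE, FALSE))
})
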