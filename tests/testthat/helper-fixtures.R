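# Programmatic fixtures shared across test files.

# recording whose channels are given signal vectors (rows)
recFromRows <- function(rows, fs, labels = NULL, tissue = "grey") {
  X <- do.call(rbind, rows)
  if (is.null(labels)) labels <- formatChannelLabel("LA", seq_len(nrow(X)))
  ieegRecording(X, fs = fs, channels = makeChannelInfo(labels, tissue = tissue))
}

sineRec <- function(freqs, fs = 512, durS = 4, phases = 0, amp = 1) {
  t <- seq(0, durS - 1 / fs, by = 1 / fs)
  phases <- rep_len(phases, length(freqs))
  rows <- Map(function(f, ph) amp * sin(2 * pi * f * t + ph), freqs, phases)
  recFromRows(rows, fs)
}

noiseRec <- function(nCh, fs = 512, durS = 4, seed = 1, sd = 1) {
  set.seed(seed)
  recFromRows(lapply(seq_len(nCh), function(i) rnorm(durS * fs, sd = sd)), fs)
}

# network with explicit symmetric weights; "re" admits any non-negative value
toyNet <- function(W, measure = "re", labels = NULL, scheme = "car") {
  if (is.null(labels)) labels <- formatChannelLabel("LA", seq_len(nrow(W)))
  connectivityNetwork(W, nodes = labels, measure = measure, scheme = scheme)
}

# small epoch set of white-noise epochs
noiseEpochs <- function(nCh = 4, fs = 256, epochS = 8, nEpochs = 2, seed = 1) {
  set.seed(seed)
  labels <- c(formatChannelLabel("LA", seq_len(ceiling(nCh / 2))),
              formatChannelLabel("RA", seq_len(floor(nCh / 2))))
  eps <- lapply(seq_len(nEpochs), function(i)
    ieegRecording(matrix(rnorm(nCh * fs * epochS), nCh), fs = fs,
                  channels = makeChannelInfo(labels, tissue = "grey")))
  epochSet(eps, epochS)
}
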