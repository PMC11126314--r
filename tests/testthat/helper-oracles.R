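# Independent brute-force estimators used as oracles. Each recomputes a
# measure from its definition with plain loops, sharing no code with the
# package internals.

oraclePearson <- function(X, fs, windowS = 2, squared = FALSE) {
  wlen <- round(windowS * fs)
  nw <- floor(ncol(X) / wlen)
  n <- nrow(X)
  acc <- matrix(0, n, n); cnt <- matrix(0, n, n)
  for (w in seq_len(nw)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- suppressWarnings(cor(X[i, idx], X[j, idx]))
      if (is.finite(r)) {
        v <- if (squared) r^2 else r
        acc[i, j] <- acc[i, j] + v; cnt[i, j] <- cnt[i, j] + 1
      }
    }
  }
  W <- acc / cnt
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- NA
  W
}

oracleXcorrPair <- function(x, y, fs, maxLagMs) {
  L <- round(maxLagMs / 1000 * fs)
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  sx <- sqrt(mean(x^2)); sy <- sqrt(mean(y^2))
  best <- 0
  for (tau in -L:L) {
    if (tau >= 0) { a <- x[(1 + tau):n]; b <- y[1:(n - tau)] }
    else { a <- x[1:(n + tau)]; b <- y[(1 - tau):n] }
    r <- sum(a * b) / ((n - abs(tau)) * sx * sy)
    best <- max(best, abs(r))
  }
  best
}

oracleCoherencePair <- function(x, y, fs, windowS, low, high,
                                squared = TRUE) {
  wlen <- round(windowS * fs)
  nw <- floor(length(x) / wlen)
  taper <- 0.5 * (1 - cos(2 * pi * (0:(wlen - 1)) / (wlen - 1)))
  nb <- floor(wlen / 2) + 1
  sxx <- syy <- numeric(nb); sxy <- complex(nb)
  for (w in seq_len(nw)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    fx <- fft((x[idx] - mean(x[idx])) * taper)[1:nb]
    fy <- fft((y[idx] - mean(y[idx])) * taper)[1:nb]
    sxx <- sxx + Mod(fx)^2; syy <- syy + Mod(fy)^2
    sxy <- sxy + fx * Conj(fy)
  }
  f <- (0:(nb - 1)) * fs / wlen
  keep <- f >= low & f <= high
  msc <- Mod(sxy[keep])^2 / (sxx[keep] * syy[keep])
  mean(if (squared) msc else sqrt(msc))
}

oraclePLVPair <- function(x, y, fs, windowS) {
  analytic <- function(v) {
    n <- length(v); F <- fft(v); h <- numeric(n)
    if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
    else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
    fft(F * h, inverse = TRUE) / n
  }
  phx <- Arg(analytic(x)); phy <- Arg(analytic(y))
  wlen <- round(windowS * fs)
  nw <- floor(length(x) / wlen)
  mean(vapply(seq_len(nw), function(w) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    Mod(mean(exp(1i * (phx[idx] - phy[idx]))))
  }, 0))
}

oracleKL <- function(x, y, nBins) {
  br <- seq(min(x, y), max(x, y), length.out = nBins + 1)
  cx <- hist(x, breaks = br, plot = FALSE)$counts + 0.5
  cy <- hist(y, breaks = br, plot = FALSE)$counts + 0.5
  p <- cx / sum(cx); q <- cy / sum(cy)
  c(pq = sum(p * log(p / q)), qp = sum(q * log(q / p)))
}

oracleREPair <- function(x, y, fs, windowS, nBins) {
  wlen <- round(windowS * fs)
  nw <- floor(length(x) / wlen)
  mean(vapply(seq_len(nw), function(w) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    max(oracleKL(x[idx], y[idx], nBins))
  }, 0))
}

# planted block-structured similarity matrix
plantedS <- function(sizes, within = 0.9, between = 0.1, noise = 0,
                     seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  S <- ifelse(outer(lab, lab, `==`), within, between)
  if (noise > 0) {
    set.seed(seed)
    E <- matrix(rnorm(n * n, sd = noise), n)
    S <- S + (E + t(E)) / 2
  }
  diag(S) <- 1
  dimnames(S) <- list(paste0("p", 1:n), paste0("p", 1:n))
  S
}
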