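# Independent oracles, written against the definitions rather than the
# package's code paths.

# dominant frequency of a real signal in cycles/sample, via the magnitude FFT
fft_peak_freq <- function(x) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(n %/% 2 + 1)]
  mag[1] <- 0                      # ignore DC
  (which.max(mag) - 1) / n
}

# ideal band-pass component of x: keep FFT bins whose frequency falls in
# [lo, hi) cycles/sample (and their conjugates), zero the rest
fft_bandpass <- function(x, lo, hi) {
  n <- length(x)
  f <- stats::fft(x)
  freq <- (seq_len(n) - 1) / n
  freq <- pmin(freq, 1 - freq)     # fold to [0, 0.5]
  f[freq < lo | freq >= hi] <- 0
  Re(stats::fft(f, inverse = TRUE)) / n
}

# naive LSSVR: full (m+1) system built elementwise and solved generically
lssvr_oracle_predict <- function(X, y, gamma, sigma2, Xnew) {
  m <- nrow(X)
  A <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m)) {
    A[1, i + 1] <- 1
    A[i + 1, 1] <- 1
    for (j in seq_len(m))
      A[i + 1, j + 1] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma2)) +
        (i == j) / gamma
  }
  sol <- qr.solve(A, c(0, y))
  b0 <- sol[1]; b <- sol[-1]
  apply(Xnew, 1, function(z) {
    b0 + sum(b * exp(-apply(X, 1, function(xi) sum((z - xi)^2)) / (2 * sigma2)))
  })
}

# greedy max-min Kennard-Stone by exhaustive candidate scan
ks_oracle <- function(X, n_train) {
  m <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(1L, 2L); bd <- -1
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(m), sel)
    dmin <- sapply(cand, function(c) min(D[c, sel]))
    sel <- c(sel, cand[which.max(dmin)])
  }
  sel
}

# small noiseless mixture data set on the UV-Vis-like grid
noiseless_mixture <- function(m = 20, seed = 0) {
  lib <- spectral_library("uvvis_oil_like", seed = 0)
  des <- sample_fractions(m, nrow(lib$pure_spectra), "dirichlet", seed = seed)
  synthesize_spectra(lib, des, noise_sd = 0, baseline_amp = 0,
                     nonlinearity = 0, seed = seed)
}
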