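# Independent oracles used across the suite. These deliberately avoid the
# package's own spectral code paths.

# Raw periodogram via stats::spec.pgram (no taper, no detrend); returns
# freqs in Hz and linear spectral estimates. Used to verify generator
# spectral content independently of the package's Welch estimator.
oracle_periodogram <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, demean = FALSE, fast = FALSE,
                          plot = FALSE)
  list(freqs = sp$freq, power = sp$spec)
}

# frequency of the strongest periodogram component
oracle_peak_freq <- function(x, fs) {
  p <- oracle_periodogram(x, fs)
  p$freqs[which.max(p$power)]
}

# Brute-force Welch estimate: non-overlapping Blackman-Harris segments,
# each transformed by an explicit O(n^2) DFT sum (no FFT), one-sided
# density scaling. Matches the contract of welch_psd() but shares no code.
oracle_welch <- function(x, fs, nfft = 1024, wlen = 844) {
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  k <- seq_len(wlen) - 1
  w <- a[1] - a[2] * cos(2 * pi * k / wlen) + a[3] * cos(4 * pi * k / wlen) -
    a[4] * cos(6 * pi * k / wlen)
  n_seg <- length(x) %/% wlen
  half <- nfft %/% 2 + 1
  # explicit DFT matrix: X_k = sum_n x_n exp(-2 pi i k n / nfft)
  W <- exp(-2i * pi * outer(0:(half - 1), 0:(nfft - 1)) / nfft)
  acc <- numeric(half)
  for (s in seq_len(n_seg)) {
    seg <- c(x[((s - 1) * wlen + 1):(s * wlen)] * w, numeric(nfft - wlen))
    X <- as.vector(W %*% seg)
    p <- Mod(X)^2 / (fs * sum(w^2))
    p[2:(half - 1)] <- 2 * p[2:(half - 1)]
    acc <- acc + p
  }
  list(freqs = (seq_len(half) - 1) * fs / nfft, power = acc / n_seg)
}

# polynomial least squares through explicit normal equations
oracle_polyfit <- function(x, y, order) {
  X <- outer(x, 0:order, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
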