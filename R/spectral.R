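# Welch log-PSD estimation, band powers, peak detection, and analytic
# forecasting of stimulation-artifact frequencies (SSH / ASH / IMH).

#' Four-term Blackman-Harris window
#'
#' Periodic (DFT-even) form with the standard minimum-sidelobe
#' coefficients (peak sidelobe -92 dB).
#'
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @export
blackman_harris <- function(n) {
  check_scalar(n, "n", 1, integerish = TRUE)
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  k <- seq_len(n) - 1
  a[1] - a[2] * cos(2 * pi * k / n) + a[3] * cos(4 * pi * k / n) -
    a[4] * cos(6 * pi * k / n)
}

#' Welch power spectral density (linear power)
#'
#' Averaged modified periodograms over non-overlapping windowed segments,
#' zero-padded to the FFT length. One-sided density scaling: values are
#' power per Hz, with the window's power (`sum(w^2)`) corrected for and
#' all bins except DC and Nyquist doubled. No per-segment detrending is
#' applied.
#'
#' With the default settings (1024-bin FFT, 844-sample Blackman-Harris
#' window, 0% overlap) a 20 s recording at 422 Hz yields exactly 10
#' averaged segments on a grid spaced 422/1024 = 0.4121 Hz.
#'
#' @param rec A [recording()], [source_signal()], or numeric vector.
#' @param cfg A [welch_config()]; its `fs` is overridden by the input's
#'   own sampling rate when the input carries one.
#' @return A list with `freqs` (Hz, length `nfft/2 + 1`), `power` (linear,
#'   per Hz), and `n_segments`.
#' @seealso [welch_logpsd()]
#' @export
welch_psd <- function(rec, cfg = welch_config()) {
  stopifnot(inherits(cfg, "welch_config"))
  if (inherits(rec, "recording") || inherits(rec, "source_signal")) {
    fs <- rec$fs
    x <- rec$samples
  } else {
    fs <- cfg$fs
    x <- as.numeric(rec)
  }
  wl <- cfg$window_len
  nfft <- cfg$nfft
  if (length(x) < wl)
    stop_config("recording (%d samples) is shorter than one %d-sample segment",
                length(x), wl)
  w <- blackman_harris(wl)
  u <- sum(w^2)
  n_seg <- length(x) %/% wl
  half <- nfft %/% 2 + 1L
  acc <- numeric(half)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * wl + 1):(s * wl)] * w
    X <- stats::fft(c(seg, numeric(nfft - wl)))
    p <- Mod(X[seq_len(half)])^2 / (fs * u)
    p[2:(half - 1)] <- 2 * p[2:(half - 1)]
    acc <- acc + p
  }
  list(freqs = (seq_len(half) - 1) * fs / nfft,
       power = acc / n_seg, n_segments = n_seg)
}

#' Welch log-power spectral density
#'
#' [welch_psd()] expressed in decibels, `10 * log10(Pxx)`.
#'
#' @inheritParams welch_psd
#' @return A `log_psd` object: list with `freqs` (Hz), `values` (dB),
#'   `fs`, `n_segments`, and `meta` copied from the input recording.
#' @export
welch_logpsd <- function(rec, cfg = welch_config()) {
  p <- welch_psd(rec, cfg)
  fs <- if (inherits(rec, "recording") || inherits(rec, "source_signal"))
    rec$fs else cfg$fs
  meta <- if (inherits(rec, "recording")) rec$meta else list()
  structure(list(freqs = p$freqs, values = 10 * log10(p$power), fs = fs,
                 n_segments = p$n_segments, welch = cfg, meta = meta),
            class = "log_psd")
}

#' Construct a log-PSD object directly
#'
#' For analyses starting from an externally computed spectrum.
#'
#' @param freqs Strictly increasing frequency grid, Hz.
#' @param values Power values in dB, same length as `freqs`.
#' @param fs Sampling rate the spectrum refers to; defaults to
#'   `2 * max(freqs)`.
#' @return A `log_psd` object.
#' @export
log_psd <- function(freqs, values, fs = 2 * max(freqs)) {
  if (length(freqs) != length(values) || any(diff(freqs) <= 0))
    stop_config("freqs must be strictly increasing and match values")
  structure(list(freqs = as.numeric(freqs), values = as.numeric(values),
                 fs = fs, n_segments = NA_integer_, welch = NULL,
                 meta = list()),
            class = "log_psd")
}

#' @export
print.log_psd <- function(x, ...) {
  cat(sprintf(
    "<log_psd> %d bins, %.4g-%.4g Hz (spacing %.4g Hz), %s segments\n",
    length(x$freqs), min(x$freqs), max(x$freqs),
    stats::median(diff(x$freqs)),
    ifelse(is.na(x$n_segments), "?", x$n_segments)))
  invisible(x)
}

#' Plot a log-PSD
#'
#' @param x A `log_psd` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.log_psd <- function(x, ...) {
  graphics::plot(x$freqs, x$values, type = "l",
                 xlab = "Frequency (Hz)", ylab = "Power (dB)", ...)
  invisible(x)
}

nearest_bin <- function(psd, f) which.min(abs(psd$freqs - f))

#' Oscillatory band schemes
#'
#' A named set of frequency windows. Two built-ins are provided:
#' * [standard_bands()]: delta 1-4, theta 4-8, alpha 8-14, beta 14-30,
#'   gamma 30-50 Hz;
#' * [adjusted_bands()]: the artifact-avoiding scheme, identical except
#'   beta 14-20 and gamma 40-50 Hz. Each adjusted window stays inside its
#'   standard counterpart, so band labels keep their conventional meaning,
#'   while the windows exclude the 32 Hz aliased shaping harmonic and the
#'   region distorted under 130 Hz stimulation sampled at 422 Hz.
#'
#' @param windows Named list of `c(f_lo, f_hi)` pairs, `f_lo < f_hi`.
#' @param name Label for the scheme.
#' @return An object of class `band_scheme`.
#' @export
band_scheme <- function(windows, name = "custom") {
  stopifnot(is.list(windows), length(windows) > 0,
            !is.null(names(windows)), all(nzchar(names(windows))))
  for (b in names(windows)) {
    w <- windows[[b]]
    if (!is.numeric(w) || length(w) != 2L || w[1] >= w[2] || w[1] < 0)
      stop_config("band '%s' must be c(f_lo, f_hi) with 0 <= f_lo < f_hi", b)
  }
  structure(list(windows = windows, name = name), class = "band_scheme")
}

#' @rdname band_scheme
#' @export
standard_bands <- function() {
  band_scheme(list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 14),
                   beta = c(14, 30), gamma = c(30, 50)),
              name = "standard")
}

#' @rdname band_scheme
#' @export
adjusted_bands <- function() {
  band_scheme(list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 14),
                   beta = c(14, 20), gamma = c(40, 50)),
              name = "adjusted")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme '%s'>\n", x$name))
  for (b in names(x$windows))
    cat(sprintf("  %-6s %g-%g Hz\n", b, x$windows[[b]][1], x$windows[[b]][2]))
  invisible(x)
}

# indices of the bins aggregated for a band: half-open [f_lo, f_hi),
# DC bin always excluded (the hardware high-pass makes it meaningless)
band_bins <- function(psd, window) {
  which(psd$freqs >= window[1] & psd$freqs < window[2] & psd$freqs > 0)
}

#' Aggregate band power from a log-PSD
#'
#' Mean or median of the dB values over the bins falling in the band's
#' half-open window `[f_lo, f_hi)`. Half-open intervals ensure adjacent
#' bands never double-count a bin; the DC bin is always excluded.
#'
#' @param psd A `log_psd`.
#' @param scheme A [band_scheme()].
#' @param band Band name, must be present in `scheme`.
#' @param agg `"mean"` or `"median"`.
#' @return Band power in dB.
#' @export
band_power <- function(psd, scheme = standard_bands(), band,
                       agg = c("mean", "median")) {
  agg <- match.arg(agg)
  stopifnot(inherits(psd, "log_psd"), inherits(scheme, "band_scheme"))
  if (!band %in% names(scheme$windows))
    stop_config("band '%s' is not in scheme '%s'", band, scheme$name)
  idx <- band_bins(psd, scheme$windows[[band]])
  if (length(idx) == 0)
    stop_config("band '%s' contains no frequency bins on this grid", band)
  if (agg == "mean") mean(psd$values[idx]) else stats::median(psd$values[idx])
}

#' Band powers for every band of a scheme
#'
#' @inheritParams band_power
#' @return A data frame with columns `band`, `f_lo`, `f_hi`, `scheme`,
#'   `aggregator`, `power_db`.
#' @export
band_power_table <- function(psd, scheme = standard_bands(),
                             agg = c("mean", "median")) {
  agg <- match.arg(agg)
  bands <- names(scheme$windows)
  data.frame(
    band = bands,
    f_lo = vapply(bands, function(b) scheme$windows[[b]][1], numeric(1)),
    f_hi = vapply(bands, function(b) scheme$windows[[b]][2], numeric(1)),
    scheme = scheme$name,
    aggregator = agg,
    power_db = vapply(bands, function(b) band_power(psd, scheme, b, agg),
                      numeric(1)),
    row.names = NULL)
}

#' Detect narrowband peaks at candidate frequencies
#'
#' For each candidate frequency, selects a peak bin within `tol_bins` bins
#' of the nearest grid bin -- the highest local maximum in that window if
#' one exists, otherwise the nearest bin itself (predicted artifacts can
#' ride the spectral-leakage skirt of a much louder neighbour, e.g. the
#' 66 Hz intermodulation harmonic as a shoulder on the 64 Hz alias, and
#' then no strict local maximum exists) -- and reports its prominence: the
#' peak's dB value minus a local background estimate. The background is
#' the *quieter* of the two flanking medians (bins from 2 bins up to
#' `neighborhood_hz` away on each side of the peak): taking the quieter
#' side makes the estimate robust to a neighbouring artifact peak whose
#' skirt contaminates one flank, while a bin that merely sits on such a
#' skirt, with no power of its own, still scores near-zero prominence at
#' its proper (nearest) bin. A candidate is `found` when the prominence
#' exceeds `threshold_db`.
#'
#' @param psd A `log_psd`.
#' @param candidates Frequencies to test, Hz (all within `[0, fs/2]`).
#' @param tol_bins Search half-width in bins around each candidate
#'   (default 1; 0 tests exactly the nearest bin).
#' @param threshold_db Prominence threshold in dB (default 6, far below
#'   the >= 20 dB excursions the model produces at default settings).
#' @param neighborhood_hz Half-width of the background neighbourhood in Hz
#'   (default 2).
#' @return Data frame with columns `freq`, `peak_freq`, `power_db`,
#'   `prominence_db`, `found`.
#' @export
find_peaks <- function(psd, candidates, tol_bins = 1L, threshold_db = 6,
                       neighborhood_hz = 2) {
  stopifnot(inherits(psd, "log_psd"), is.numeric(candidates))
  nyq <- max(psd$freqs)
  if (any(candidates < 0 | candidates > nyq))
    stop_config("candidates must lie within [0, %g] Hz", nyq)
  n <- length(psd$freqs)
  res <- lapply(candidates, function(f) {
    ib <- nearest_bin(psd, f)
    lo <- max(1L, ib - tol_bins)
    hi <- min(n, ib + tol_bins)
    win <- lo:hi
    is_lmax <- vapply(win, function(j) {
      (j == 1L || psd$values[j] >= psd$values[j - 1L]) &&
        (j == n || psd$values[j] >= psd$values[j + 1L])
    }, logical(1))
    peak <- if (any(is_lmax)) {
      cand <- win[is_lmax]
      cand[which.max(psd$values[cand])]
    } else ib
    near <- abs(psd$freqs - psd$freqs[peak]) <= neighborhood_hz
    flank_left <- which(near & seq_len(n) <= peak - 2L)
    flank_right <- which(near & seq_len(n) >= peak + 2L)
    meds <- c(if (length(flank_left)) stats::median(psd$values[flank_left]),
              if (length(flank_right)) stats::median(psd$values[flank_right]))
    bg <- if (length(meds)) min(meds) else -Inf
    prom <- psd$values[peak] - bg
    data.frame(freq = f, peak_freq = psd$freqs[peak],
               power_db = psd$values[peak], prominence_db = prom,
               found = prom > threshold_db)
  })
  do.call(rbind, res)
}

#' Fold a frequency into the sampled band
#'
#' Aliasing arithmetic for undersampling: a component at `f` Hz sampled at
#' `fs` Hz appears at `r = f mod fs` if `r <= fs/2`, else at `fs - r`.
#' Vectorised over `f`; idempotent.
#'
#' @param f Frequencies, Hz (non-negative).
#' @param fs Sampling rate, Hz.
#' @return Aliased frequencies in `[0, fs/2]`.
#' @examples
#' alias_frequency(390, 422)  # 32: the 3rd stimulation harmonic's alias
#' alias_frequency(910, 422)  # 66: the 7th harmonic's alias
#' @export
alias_frequency <- function(f, fs) {
  check_scalar(fs, "fs", 0, strict_lower = TRUE)
  if (any(f < 0)) stop_config("frequencies must be non-negative")
  r <- f %% fs
  ifelse(r <= fs / 2, r, fs - r)
}

#' Forecast stimulation-artifact frequencies
#'
#' Computes, for a stimulation configuration and output sampling rate, the
#' three families of predicted narrowband artifacts:
#' * `ssh`: retained stimulation shaping harmonics that lie below the
#'   Nyquist rate (observed at their true frequencies),
#' * `ash`: aliases of retained harmonics above the Nyquist rate (present
#'   even with a perfectly linear amplifier),
#' * `imh`: aliases of harmonics beyond the waveform's truncation order,
#'   up to `imh_max_order` -- absent from the stimulation waveform itself,
#'   these can only be regenerated by amplifier nonlinearity, so their
#'   presence indicates gain compression.
#'
#' @param stim A [stim_config()].
#' @param fs Output (recorded) sampling rate, Hz.
#' @param imh_max_order Highest harmonic order forecast as IMH; must
#'   exceed `stim$n_harmonics` (default `n_harmonics + 2`).
#' @return An `artifact_forecast` object: list with numeric vectors
#'   `ssh`, `ash`, `imh` (Hz), plus the generating parameters.
#' @examples
#' predict_artifacts(stim_config(f_T = 130), fs = 422, imh_max_order = 8)
#' @export
predict_artifacts <- function(stim, fs,
                              imh_max_order = stim$n_harmonics + 2L) {
  stopifnot(inherits(stim, "stim_config"))
  check_scalar(fs, "fs", 0, strict_lower = TRUE)
  check_scalar(imh_max_order, "imh_max_order", 1, integerish = TRUE)
  if (imh_max_order <= stim$n_harmonics)
    stop_config("imh_max_order (%d) must exceed n_harmonics (%d)",
                imh_max_order, stim$n_harmonics)
  k <- seq_len(stim$n_harmonics)
  hf <- k * stim$f_T
  k_imh <- (stim$n_harmonics + 1L):imh_max_order
  structure(
    list(ssh = hf[hf <= fs / 2],
         ash = alias_frequency(hf[hf > fs / 2], fs),
         imh = alias_frequency(k_imh * stim$f_T, fs),
         f_T = stim$f_T, fs = fs, n_harmonics = stim$n_harmonics,
         imh_max_order = as.integer(imh_max_order)),
    class = "artifact_forecast")
}

#' @export
print.artifact_forecast <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(round(v, 2), collapse = ", ")
    else "(none)"
  cat(sprintf("<artifact_forecast> f_T %g Hz sampled at %g Hz\n", x$f_T, x$fs))
  cat("  SSH:", fmt(x$ssh), "\n  ASH:", fmt(x$ash), "\n  IMH:", fmt(x$imh),
      "\n")
  invisible(x)
}
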