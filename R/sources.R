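# Brain-layer signal generators: oscillation, 1/f background, stimulation
# artifact (truncated Fourier series) and the device over-range marker, all
# on the high-rate "tissue" grid.

#' Source signal container
#'
#' A uniformly sampled voltage series with its sampling rate and a label
#' identifying which model source it is.
#'
#' @param samples Numeric vector of voltage samples (model units).
#' @param fs Sampling rate in Hz.
#' @param label One of `"x1"`, `"x3"`, `"stim"`, `"orm"`, `"diff"`.
#' @param meta Optional named list of provenance metadata.
#' @return An object of class `source_signal`.
#' @export
source_signal <- function(samples, fs, label = "x1", meta = list()) {
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop_config("samples must be a finite numeric vector")
  check_scalar(fs, "fs", 0, strict_lower = TRUE)
  stopifnot(is.character(label), length(label) == 1L, is.list(meta))
  structure(list(samples = as.numeric(samples), fs = fs, label = label,
                 meta = meta),
            class = "source_signal")
}

#' @export
print.source_signal <- function(x, ...) {
  cat(sprintf("<source_signal '%s'> %d samples @ %g Hz (%.3g s), RMS %.3g\n",
              x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs, sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
as.data.frame.source_signal <- function(x, ...) {
  data.frame(time_s = (seq_along(x$samples) - 1) / x$fs, value = x$samples)
}

# time axis for n samples at fs, starting at t = 0
time_grid <- function(fs, duration) {
  n <- round(fs * duration)
  (seq_len(n) - 1) / fs
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a stationary neural oscillation
#'
#' A pure sinusoid with zero initial phase: `amplitude * sin(2 pi f t)`.
#'
#' @param f Oscillation frequency, Hz; must lie below `fs / 2`.
#' @param amplitude Amplitude in model units.
#' @param fs Sampling rate, Hz.
#' @param duration Duration in seconds.
#' @return A [source_signal()] of `round(fs * duration)` samples.
#' @examples
#' osc <- gen_oscillation(15, 2e-3, 4220, 20)
#' length(osc$samples)  # 84400
#' @export
gen_oscillation <- function(f, amplitude, fs, duration) {
  check_scalar(fs, "fs", 0, strict_lower = TRUE)
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  check_scalar(f, "f", 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", 0)
  if (f >= fs / 2)
    stop_config("oscillation at %g Hz would alias: Nyquist is %g Hz",
                f, fs / 2)
  t <- time_grid(fs, duration)
  source_signal(amplitude * sin(2 * pi * f * t), fs, "x1",
                meta = list(f = f, amplitude = amplitude))
}

#' Generate 1/f (pink) background noise
#'
#' Zero-mean Gaussian noise whose one-sided power spectral density is
#' `strength^2 / f`, synthesised by frequency-domain shaping: independent
#' complex-Gaussian Fourier coefficients are drawn with magnitudes
#' proportional to `f^(-1/2)` and inverse-transformed. The construction is
#' exact (the expected periodogram follows the 1/f law at every nonzero
#' bin) and fully determined by `seed`.
#'
#' @param strength Noise scale: the PSD at 1 Hz is `strength^2` per Hz.
#' @param fs Sampling rate, Hz.
#' @param duration Duration, seconds.
#' @param seed RNG seed; independent seeds give independent realisations.
#' @return A [source_signal()] with zero DC component.
#' @export
gen_pink_noise <- function(strength, fs, duration, seed = 1L) {
  check_scalar(strength, "strength", 0)
  check_scalar(fs, "fs", 0, strict_lower = TRUE)
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  n <- round(fs * duration)
  if (strength == 0)
    return(source_signal(numeric(n), fs, "noise",
                         meta = list(strength = 0, seed = seed)))
  nf <- (n - 1) %/% 2                      # positive, non-Nyquist bins
  f <- (1:nf) * fs / n
  # E|X_k|^2 = S(f_k) * n * fs / 2 gives a one-sided periodogram that
  # matches the target density S(f) = strength^2 / f.
  sigma <- sqrt(strength^2 / f * n * fs / 2)
  spec <- with_seed(seed, {
    re <- stats::rnorm(nf + (n %% 2 == 0), sd = sqrt(0.5))
    im <- stats::rnorm(nf, sd = sqrt(0.5))
    list(re = re, im = im)
  })
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- complex(real = spec$re[1:nf],
                              imaginary = spec$im) * sigma
  if (n %% 2 == 0) {
    # Nyquist coefficient must be real for a real signal
    f_nyq <- fs / 2
    full[n / 2 + 1] <- sqrt(strength^2 / f_nyq * n * fs / 2) *
      spec$re[nf + 1] * sqrt(2)
  }
  idx <- 2:(nf + 1)
  full[n + 2 - idx] <- Conj(full[idx])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  source_signal(x, fs, "noise", meta = list(strength = strength, seed = seed))
}

#' Relative amplitudes of the stimulation harmonics
#'
#' Weight of harmonic k under the configured rule, normalised so harmonic 1
#' has weight 1. The `"pulse"` rule uses the Fourier-series magnitudes of a
#' biphasic rectangular pulse of per-phase width `pulse_width` repeating at
#' `f_T`: `|c_k|` is proportional to `sin^2(pi k f_T w) / k`. For the
#' clinical 130 Hz / 90 us setting these weights grow roughly linearly over
#' the first six harmonics (a biphasic pulse pair behaves like a doublet,
#' whose spectrum rises before rolling off near 1 / (2 w)).
#'
#' @param stim A [stim_config()].
#' @return Numeric vector of length `stim$n_harmonics`.
#' @export
harmonic_weights <- function(stim) {
  stopifnot(inherits(stim, "stim_config"))
  k <- seq_len(stim$n_harmonics)
  w <- switch(stim$harmonic_decay,
    pulse = sin(pi * k * stim$f_T * stim$pulse_width)^2 / k,
    inv_k = 1 / k)
  w / w[1]
}

#' Generate the stimulation artifact waveform
#'
#' A truncated Fourier series of sinusoids at multiples of the stimulation
#' base frequency (the stimulation shaping harmonics, SSH). Harmonic k has
#' amplitude `amplitude * harmonic_weights(stim)[k]` and zero initial
#' phase; harmonic 1 carries exactly the configured stimulation amplitude.
#'
#' All retained harmonics must be representable at `fs`; a harmonic at or
#' above `fs / 2` raises an error rather than being dropped silently.
#'
#' @param stim A [stim_config()].
#' @param fs Sampling rate, Hz.
#' @param duration Duration, seconds.
#' @return A [source_signal()] labelled `"stim"`, with the configured
#'   amplitude recorded in its `meta`.
#' @export
gen_stim_artifact <- function(stim, fs, duration) {
  stopifnot(inherits(stim, "stim_config"))
  check_scalar(fs, "fs", 0, strict_lower = TRUE)
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  f_max <- stim$n_harmonics * stim$f_T
  if (f_max >= fs / 2)
    stop_config(
      "harmonic %d at %g Hz is not representable at fs = %g Hz (Nyquist %g Hz)",
      stim$n_harmonics, f_max, fs, fs / 2)
  t <- time_grid(fs, duration)
  x <- numeric(length(t))
  if (stim$amplitude > 0) {
    w <- harmonic_weights(stim)
    for (k in seq_len(stim$n_harmonics))
      x <- x + stim$amplitude * w[k] * sin(2 * pi * k * stim$f_T * t)
  }
  source_signal(x, fs, "stim",
                meta = list(amplitude = stim$amplitude, f_T = stim$f_T,
                            n_harmonics = stim$n_harmonics))
}

#' Generate the over-range-marker tone
#'
#' The device injects a constant-amplitude marker tone (105.5 Hz on the
#' modelled hardware); loss of its spectral peak in a recording indicates
#' amplifier saturation.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Duration, seconds.
#' @param amplitude Tone amplitude in model units.
#' @param freq Tone frequency, Hz (default 105.5).
#' @return A [source_signal()] labelled `"orm"`.
#' @export
gen_orm <- function(fs, duration, amplitude, freq = 105.5) {
  check_scalar(freq, "freq", 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", 0)
  if (freq >= fs / 2)
    stop_config("ORM at %g Hz is above the Nyquist rate %g Hz", freq, fs / 2)
  t <- time_grid(fs, duration)
  source_signal(amplitude * sin(2 * pi * freq * t), fs, "orm",
                meta = list(freq = freq, amplitude = amplitude))
}

#' Assemble all brain-layer sources
#'
#' Builds the four signals seen by the lead and device layers, on a common
#' high-rate grid:
#' * `x1`: the 15 Hz-class oscillation plus an independent 1/f background
#'   (seed `cfg$seed`),
#' * `x3`: a second, independent 1/f background only (seed `cfg$seed + 1`),
#' * `S`: the stimulation artifact waveform,
#' * `orm`: the device marker tone.
#'
#' @param cfg A [brain_config()].
#' @param stim A [stim_config()].
#' @return A named list of four [source_signal()] objects
#'   (`x1`, `x3`, `S`, `orm`).
#' @export
assemble_sources <- function(cfg, stim) {
  stopifnot(inherits(cfg, "brain_config"), inherits(stim, "stim_config"))
  osc <- gen_oscillation(cfg$f_osc, cfg$osc_amplitude, cfg$fs_hi,
                         cfg$duration)
  p1 <- gen_pink_noise(cfg$pink_strength, cfg$fs_hi, cfg$duration,
                       seed = cfg$seed)
  p3 <- gen_pink_noise(cfg$pink_strength, cfg$fs_hi, cfg$duration,
                       seed = cfg$seed + 1L)
  x1 <- source_signal(osc$samples + p1$samples, cfg$fs_hi, "x1",
                      meta = list(seed = cfg$seed))
  x3 <- source_signal(p3$samples, cfg$fs_hi, "x3",
                      meta = list(seed = cfg$seed + 1L))
  S <- gen_stim_artifact(stim, cfg$fs_hi, cfg$duration)
  orm <- gen_orm(cfg$fs_hi, cfg$duration, cfg$orm_amplitude, cfg$orm_freq)
  list(x1 = x1, x3 = x3, S = S, orm = orm)
}
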