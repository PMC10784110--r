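#' @keywords internal
stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_config("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stop_config("`%s` must be >= %g", name, lower)
  if (x > upper)
    stop_config("`%s` must be <= %g", name, upper)
  if (integerish && x != round(x))
    stop_config("`%s` must be a whole number", name)
  invisible(x)
}

#' Brain-layer configuration
#'
#' Parameters of the tissue-side signal generators: a stationary neural
#' oscillation, independent 1/f (pink) backgrounds for the two recorded
#' sources, and the device over-range-marker (ORM) tone. Signals are
#' synthesised on a high-rate grid running ten times faster than the
#' device output rate, so that undersampling by the ADC can alias
#' stimulation harmonics into the recorded band.
#'
#' Amplitudes are dimensionless model units; only ratios between the
#' oscillation, the 1/f background and the leaked stimulation artifact
#' matter for any spectral quantity computed downstream.
#'
#' @param fs_hi High-rate sampling grid in Hz (default 4220; ten times the
#'   422 Hz device output rate).
#' @param duration Length of the generated signals in seconds (default 20).
#' @param f_osc Oscillation frequency in Hz (default 15).
#' @param osc_amplitude Oscillation amplitude in model units (default 2e-3).
#' @param pink_strength Scale of the 1/f background: the one-sided power
#'   spectral density of the noise is `pink_strength^2 / f` (default 1e-3).
#' @param orm_freq Over-range-marker frequency in Hz (default 105.5).
#' @param orm_amplitude Constant ORM tone amplitude in model units
#'   (default 5e-3: the marker is a deliberate device signal, injected
#'   well above the 1/f floor so it is plainly visible in every
#'   recording, as on the hardware).
#' @param seed RNG seed for the 1/f components. The second source uses
#'   `seed + 1` so the two backgrounds are independent.
#' @return An object of class `brain_config`.
#' @seealso [assemble_sources()], [simulate_recording()]
#' @export
brain_config <- function(fs_hi = 4220, duration = 20, f_osc = 15,
                         osc_amplitude = 2e-3, pink_strength = 1e-3,
                         orm_freq = 105.5, orm_amplitude = 5e-3,
                         seed = 1L) {
  check_scalar(fs_hi, "fs_hi", 0, strict_lower = TRUE)
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  check_scalar(f_osc, "f_osc", 0, strict_lower = TRUE)
  check_scalar(osc_amplitude, "osc_amplitude", 0)
  check_scalar(pink_strength, "pink_strength", 0)
  check_scalar(orm_freq, "orm_freq", 0, strict_lower = TRUE)
  check_scalar(orm_amplitude, "orm_amplitude", 0)
  check_scalar(seed, "seed", integerish = TRUE)
  if (f_osc >= fs_hi / 2)
    stop_config("f_osc (%g Hz) must be below the Nyquist rate %g Hz",
                f_osc, fs_hi / 2)
  if (orm_freq >= (fs_hi / 10) / 2)
    stop_config(
      "orm_freq (%g Hz) must be below the decimated Nyquist rate %g Hz",
      orm_freq, fs_hi / 20)
  structure(
    list(fs_hi = fs_hi, duration = duration, f_osc = f_osc,
         osc_amplitude = osc_amplitude, pink_strength = pink_strength,
         orm_freq = orm_freq, orm_amplitude = orm_amplitude,
         seed = as.integer(seed)),
    class = "brain_config")
}

#' Stimulation configuration
#'
#' The therapeutic stimulation waveform is modelled as a truncated Fourier
#' series: `n_harmonics` sinusoids at multiples of the base frequency
#' `f_T`, whose relative amplitudes follow a configurable weighting rule.
#' These harmonics are the stimulation shaping harmonics (SSH); those above
#' the device Nyquist rate fold back into the recorded band as aliased
#' shaping harmonics (ASH) after decimation.
#'
#' @param f_T Stimulation base frequency in Hz (default 130, the standard
#'   therapeutic rate).
#' @param amplitude Stimulation voltage in volts; the clinical protocol
#'   sweeps 0-8 V (default 0, i.e. stimulation off).
#' @param n_harmonics Truncation order of the Fourier series (default 6).
#'   With 422 Hz output sampling the six retained harmonics alias to
#'   130, 162, 32, 98, 194 and 64 Hz; the 7th harmonic (66 Hz alias) is
#'   absent from the waveform and can only be regenerated by amplifier
#'   nonlinearity, which is what makes 66 Hz compression-specific.
#' @param harmonic_decay Weighting rule for harmonic k: `"pulse"` uses the
#'   Fourier magnitudes of a biphasic rectangular pulse of width
#'   `pulse_width` at `f_T` (`sin^2(pi k f_T w) / k`, normalised so
#'   harmonic 1 has weight 1); `"inv_k"` uses 1/k.
#' @param pulse_width Per-phase pulse width in seconds used by the
#'   `"pulse"` rule (default 90e-6, the clinical setting).
#' @return An object of class `stim_config`.
#' @seealso [gen_stim_artifact()], [harmonic_weights()], [predict_artifacts()]
#' @export
stim_config <- function(f_T = 130, amplitude = 0, n_harmonics = 6L,
                        harmonic_decay = c("pulse", "inv_k"),
                        pulse_width = 90e-6) {
  harmonic_decay <- match.arg(harmonic_decay)
  check_scalar(f_T, "f_T", 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", 0)
  check_scalar(n_harmonics, "n_harmonics", 1, integerish = TRUE)
  check_scalar(pulse_width, "pulse_width", 0, strict_lower = TRUE)
  structure(
    list(f_T = f_T, amplitude = amplitude,
         n_harmonics = as.integer(n_harmonics),
         harmonic_decay = harmonic_decay, pulse_width = pulse_width),
    class = "stim_config")
}

#' Lead (electrode) model
#'
#' Two recording electrodes flanking the stimulation electrode, each with a
#' purely resistive impedance. Their absolute difference -- the impedance
#' mismatch -- controls how much stimulation artifact survives common-mode
#' rejection in the differential stage.
#'
#' @param Z1,Z3 Electrode resistances in ohms (defaults 1000 and 2000,
#'   giving the 1000 ohm "typical" mismatch at which 5 V stimulation leaks
#'   0.5 V into the channel).
#' @param Z_b Internal channel impedance in ohms (default 1e4).
#' @return An object of class `lead_model`.
#' @seealso [leakage_amplitude()], [impedance_mismatch()]
#' @export
lead_model <- function(Z1 = 1000, Z3 = 2000, Z_b = 1e4) {
  check_scalar(Z1, "Z1", 0)
  check_scalar(Z3, "Z3", 0)
  check_scalar(Z_b, "Z_b", 0, strict_lower = TRUE)
  structure(list(Z1 = Z1, Z3 = Z3, Z_b = Z_b), class = "lead_model")
}

#' Amplifier configuration
#'
#' The signal amplifier after the ideal differential stage. Three models of
#' gain compression are supported: a fully linear amplifier, hard clipping
#' (piece-wise linear saturation) and soft clipping, `g2 * tanh(g1 * v)`,
#' the most realistic model of gradual gain compression.
#'
#' @param model One of `"soft_clip"`, `"linear"`, `"hard_clip"`.
#' @param g1 Pre-nonlinearity gain (default 1).
#' @param g2 Post-nonlinearity gain (default 1).
#' @param clip_level Saturation bound in model volts, used only by
#'   `"hard_clip"` (default 1).
#' @return An object of class `amplifier_config`.
#' @seealso [soft_clip()], [hard_clip()], [apply_amplifier()]
#' @export
amplifier_config <- function(model = c("soft_clip", "linear", "hard_clip"),
                             g1 = 1, g2 = 1, clip_level = 1) {
  model <- match.arg(model)
  check_scalar(g1, "g1", 0, strict_lower = TRUE)
  check_scalar(g2, "g2", 0, strict_lower = TRUE)
  if (model == "hard_clip") {
    if (is.null(clip_level))
      stop_config("clip_level is required for the hard_clip amplifier")
    check_scalar(clip_level, "clip_level", 0, strict_lower = TRUE)
  }
  structure(list(model = model, g1 = g1, g2 = g2, clip_level = clip_level),
            class = "amplifier_config")
}

#' ADC configuration
#'
#' The analog-to-digital converter is modelled as plain decimation: every
#' `decimation`-th sample is kept, with no anti-alias filter by default.
#' Undersampling the residual stimulation artifact is the modelled
#' phenomenon -- it is what folds the shaping harmonics into the recorded
#' band -- so the default decimation must not be band-limited. An optional
#' first-order 100 Hz low-pass (mirroring the device's hardware filter) can
#' be applied before decimation.
#'
#' @param decimation Integer decimation factor (default 10: 4220 -> 422 Hz).
#' @param anti_alias Apply a first-order 100 Hz low-pass before decimation
#'   (default `FALSE`).
#' @return An object of class `adc_config`.
#' @export
adc_config <- function(decimation = 10L, anti_alias = FALSE) {
  check_scalar(decimation, "decimation", 1, integerish = TRUE)
  stopifnot(is.logical(anti_alias), length(anti_alias) == 1L)
  structure(list(decimation = as.integer(decimation),
                 anti_alias = anti_alias),
            class = "adc_config")
}

#' Welch estimator configuration
#'
#' Settings for the Welch power-spectral-density estimate used throughout:
#' 1024 FFT bins, non-overlapping 844-sample segments, Blackman-Harris
#' window. On 422 Hz recordings this gives a grid spacing of
#' 422/1024 = 0.4121 Hz, which places the 105.5 Hz over-range marker
#' exactly on bin 256.
#'
#' @param fs Sampling rate of the recordings to be analysed, Hz.
#' @param nfft FFT length (default 1024).
#' @param window_len Segment/window length in samples, zero-padded to
#'   `nfft` (default 844).
#' @return An object of class `welch_config`.
#' @seealso [welch_logpsd()]
#' @export
welch_config <- function(fs = 422, nfft = 1024L, window_len = 844L) {
  check_scalar(fs, "fs", 0, strict_lower = TRUE)
  check_scalar(nfft, "nfft", 1, integerish = TRUE)
  check_scalar(window_len, "window_len", 1, integerish = TRUE)
  if (window_len > nfft)
    stop_config("window_len (%d) must not exceed nfft (%d)",
                window_len, nfft)
  structure(list(fs = fs, nfft = as.integer(nfft),
                 window_len = as.integer(window_len)),
            class = "welch_config")
}

#' Mitigation pipeline configuration
#'
#' Settings for the compression-mitigation pipeline: polynomial baseline
#' order and fit range, band scheme and aggregator.
#'
#' The default fit range is capped at 105 Hz, just below the 105.5 Hz
#' over-range marker, so the constant device tone cannot steer the
#' baseline; pass `fit_range = c(1, 211)` for a full-range fit.
#'
#' @param poly_order Order of the polynomial baseline (default 4).
#' @param fit_range Two-element Hz window over which the baseline is fit
#'   (default `c(1, 105)`).
#' @param scheme A [band_scheme()]; default [adjusted_bands()].
#' @param aggregator `"median"` (default) or `"mean"`.
#' @param log_freq Fit the polynomial against log10(frequency) instead of
#'   frequency in Hz (default `FALSE`, i.e. a linear frequency axis).
#' @return An object of class `mitigation_config`.
#' @seealso [fit_baseline()], [mitigate()]
#' @export
mitigation_config <- function(poly_order = 4L, fit_range = c(1, 105),
                              scheme = adjusted_bands(),
                              aggregator = c("median", "mean"),
                              log_freq = FALSE) {
  aggregator <- match.arg(aggregator)
  check_scalar(poly_order, "poly_order", 0, integerish = TRUE)
  if (!is.numeric(fit_range) || length(fit_range) != 2L ||
      any(!is.finite(fit_range)) || fit_range[1] <= 0 ||
      fit_range[2] <= fit_range[1])
    stop_config("fit_range must be c(lo, hi) with 0 < lo < hi")
  stopifnot(inherits(scheme, "band_scheme"),
            is.logical(log_freq), length(log_freq) == 1L)
  structure(list(poly_order = as.integer(poly_order),
                 fit_range = as.numeric(fit_range), scheme = scheme,
                 aggregator = aggregator, log_freq = log_freq),
            class = "mitigation_config")
}

#' Gain compression ratio configuration
#'
#' Frequencies of the aliased shaping harmonic (ASH) and intermodulation
#' harmonic (IMH) whose log-power ratio grades compression. Under 130 Hz
#' stimulation sampled at 422 Hz these default to 64 Hz (the 6th harmonic's
#' alias, present even with a perfectly linear amplifier) and 66 Hz (the
#' 7th harmonic's alias, which only amplifier nonlinearity can create).
#'
#' @param f_ash ASH frequency in Hz (default 64).
#' @param f_imh IMH frequency in Hz (default 66).
#' @param bandwidth_bins Half-width, in frequency bins, of the window
#'   around each target in which the peak power is taken (default 1).
#' @return An object of class `gcr_config`.
#' @seealso [compute_gcr()]
#' @export
gcr_config <- function(f_ash = 64, f_imh = 66, bandwidth_bins = 1L) {
  check_scalar(f_ash, "f_ash", 0)
  check_scalar(f_imh, "f_imh", 0)
  check_scalar(bandwidth_bins, "bandwidth_bins", 0, integerish = TRUE)
  if (f_ash == f_imh) stop_config("f_ash and f_imh must differ")
  structure(list(f_ash = f_ash, f_imh = f_imh,
                 bandwidth_bins = as.integer(bandwidth_bins)),
            class = "gcr_config")
}

#' @export
print.brain_config <- function(x, ...) {
  cat(sprintf(
    "<brain_config> %g Hz grid, %g s, %g Hz oscillation (amp %g), 1/f %g, ORM %g Hz (amp %g), seed %d\n",
    x$fs_hi, x$duration, x$f_osc, x$osc_amplitude, x$pink_strength,
    x$orm_freq, x$orm_amplitude, x$seed))
  invisible(x)
}

#' @export
print.stim_config <- function(x, ...) {
  cat(sprintf(
    "<stim_config> f_T %g Hz, amplitude %g V, %d harmonics (%s weighting)\n",
    x$f_T, x$amplitude, x$n_harmonics, x$harmonic_decay))
  invisible(x)
}

#' @export
print.lead_model <- function(x, ...) {
  cat(sprintf("<lead_model> Z1 %g ohm, Z3 %g ohm (mismatch %g), Z_b %g ohm\n",
              x$Z1, x$Z3, abs(x$Z1 - x$Z3), x$Z_b))
  invisible(x)
}

#' @export
print.amplifier_config <- function(x, ...) {
  extra <- if (x$model == "hard_clip")
    sprintf(", clip_level %g", x$clip_level) else ""
  cat(sprintf("<amplifier_config> %s, g1 %g, g2 %g%s\n",
              x$model, x$g1, x$g2, extra))
  invisible(x)
}
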