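# Device layers: differential stage with mismatch-dependent artifact
# leakage, the signal amplifier (linear / hard clip / soft clip), and the
# undersampling ADC.

#' Recording container
#'
#' A simulated or loaded differential LFP: a uniformly sampled voltage
#' series, its sampling rate and the full provenance metadata (all configs
#' and seeds when produced by [simulate_recording()]).
#'
#' @param samples Numeric vector of voltage samples.
#' @param fs Sampling rate, Hz.
#' @param meta Named list of metadata.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, meta = list()) {
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop_config("samples must be a finite numeric vector")
  check_scalar(fs, "fs", 0, strict_lower = TRUE)
  stopifnot(is.list(meta))
  structure(list(samples = as.numeric(samples), fs = fs, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  amp <- x$meta$stim_amplitude
  cat(sprintf("<recording> %d samples @ %g Hz (%.3g s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (!is.null(amp)) sprintf(", stim %g V", amp) else ""))
  invisible(x)
}

#' @export
as.data.frame.recording <- function(x, ...) {
  data.frame(time_s = (seq_along(x$samples) - 1) / x$fs, value = x$samples)
}

#' Leaked artifact amplitude after common-mode rejection
#'
#' How much of the stimulation voltage survives the differential stage.
#' With perfectly matched electrodes the stimulation is purely common-mode
#' and cancels; with mismatch `|Z1 - Z3|` the leaked amplitude follows a
#' voltage-divider-style law through the device calibration point
#' (0.5 V leaked at 5 V stimulation and 1000 ohm mismatch, i.e. 10%
#' leakage at the typical mismatch):
#'
#'   `A_d = stim_amplitude * min(1, |Z1 - Z3| / Z_b)`
#'
#' saturating at the full stimulation amplitude once the mismatch reaches
#' the internal channel impedance.
#'
#' @param stim_amplitude Stimulation voltage, V.
#' @param lead A [lead_model()].
#' @return Leaked amplitude in model volts.
#' @examples
#' leakage_amplitude(5, lead_model(Z1 = 1000, Z3 = 2000, Z_b = 1e4))  # 0.5
#' @export
leakage_amplitude <- function(stim_amplitude, lead) {
  stopifnot(inherits(lead, "lead_model"))
  check_scalar(stim_amplitude, "stim_amplitude", 0)
  stim_amplitude * min(1, abs(lead$Z1 - lead$Z3) / lead$Z_b)
}

#' Differential amplifier stage
#'
#' Subtracts the two electrode signals (infinite common-mode rejection for
#' the neural sources), adds the leaked stimulation artifact scaled so that
#' its peak equals [leakage_amplitude()], and injects the device-side
#' over-range marker unattenuated (it is generated behind the differential
#' stage, so it is never differenced away):
#'
#'   `out = (x1 - x3) + A_d / max|S| * S + orm`
#'
#' @param x1,x3 Neural [source_signal()]s on the same grid.
#' @param S Stimulation artifact [source_signal()] (its `meta$amplitude`
#'   supplies the stimulation voltage for the leakage law).
#' @param orm Over-range-marker [source_signal()].
#' @param lead A [lead_model()].
#' @return A [source_signal()] labelled `"diff"`.
#' @export
differential_stage <- function(x1, x3, S, orm, lead) {
  stopifnot(inherits(x1, "source_signal"), inherits(x3, "source_signal"),
            inherits(S, "source_signal"), inherits(orm, "source_signal"),
            inherits(lead, "lead_model"))
  sigs <- list(x1, x3, S, orm)
  n <- vapply(sigs, function(s) length(s$samples), integer(1))
  fs <- vapply(sigs, function(s) s$fs, numeric(1))
  if (length(unique(n)) != 1L || length(unique(fs)) != 1L)
    stop("all inputs must share length and sampling rate", call. = FALSE)
  stim_amplitude <- S$meta$amplitude
  if (is.null(stim_amplitude)) stim_amplitude <- 0
  s_peak <- max(abs(S$samples))
  leaked <- if (s_peak > 0) {
    leakage_amplitude(stim_amplitude, lead) / s_peak * S$samples
  } else {
    numeric(length(S$samples))
  }
  source_signal(x1$samples - x3$samples + leaked + orm$samples,
                x1$fs, "diff",
                meta = list(stim_amplitude = stim_amplitude,
                            Z1 = lead$Z1, Z3 = lead$Z3))
}

#' Soft-clipping amplifier
#'
#' The tanh gain-compression model: `g2 * tanh(g1 * v)`, elementwise.
#' Bounded in (-g2, g2), odd-symmetric, and indistinguishable from a
#' linear amplifier for small inputs (`tanh(x) ~ x` as `x -> 0`).
#'
#' @param v Numeric vector (model volts).
#' @param amp An [amplifier_config()] with `model = "soft_clip"`.
#' @return Numeric vector of the same length.
#' @export
soft_clip <- function(v, amp) {
  stopifnot(inherits(amp, "amplifier_config"))
  if (amp$model != "soft_clip")
    stop_config("soft_clip() requires an amplifier with model = 'soft_clip'")
  amp$g2 * tanh(amp$g1 * v)
}

#' Hard-clipping amplifier
#'
#' Piece-wise linear saturation: `g2 * clamp(g1 * v, -clip_level,
#' clip_level)`. Below the clip level it is exactly linear.
#'
#' @param v Numeric vector.
#' @param amp An [amplifier_config()] with `model = "hard_clip"`.
#' @return Numeric vector of the same length.
#' @export
hard_clip <- function(v, amp) {
  stopifnot(inherits(amp, "amplifier_config"))
  if (amp$model != "hard_clip")
    stop_config("hard_clip() requires an amplifier with model = 'hard_clip'")
  if (is.null(amp$clip_level))
    stop_config("clip_level is required for the hard_clip amplifier")
  amp$g2 * pmin(pmax(amp$g1 * v, -amp$clip_level), amp$clip_level)
}

#' Apply the configured amplifier model
#'
#' Dispatches on `amp$model`: linear (`g2 * g1 * v`), [hard_clip()] or
#' [soft_clip()].
#'
#' @param v Numeric vector.
#' @param amp An [amplifier_config()].
#' @return Numeric vector of the same length.
#' @export
apply_amplifier <- function(v, amp) {
  stopifnot(inherits(amp, "amplifier_config"))
  switch(amp$model,
    linear = amp$g2 * amp$g1 * v,
    soft_clip = soft_clip(v, amp),
    hard_clip = hard_clip(v, amp))
}

#' ADC downsampling
#'
#' Models the analog-to-digital converter as plain decimation: every
#' `decimation`-th sample is kept (starting from the first), with no
#' anti-alias filtering by default -- the aliasing of residual stimulation
#' harmonics by this undersampling is the phenomenon under study. A
#' trailing remainder that does not fill a decimation step is truncated.
#' If `adc$anti_alias` is set, a first-order 100 Hz low-pass is applied
#' before decimation.
#'
#' @param v A [source_signal()], or a numeric vector with `fs_hi` given.
#' @param adc An [adc_config()].
#' @param fs_hi Sampling rate of `v` in Hz when `v` is a bare vector.
#' @return A [recording()] at `fs_hi / decimation` Hz.
#' @export
adc_decimate <- function(v, adc, fs_hi = NULL) {
  stopifnot(inherits(adc, "adc_config"))
  if (inherits(v, "source_signal")) {
    fs_hi <- v$fs
    v <- v$samples
  }
  if (is.null(fs_hi)) stop_config("fs_hi is required for bare numeric input")
  if (adc$anti_alias) {
    # bilinear-transform first-order RC low-pass at 100 Hz
    fc <- 100
    a <- exp(-2 * pi * fc / fs_hi)
    v <- stats::filter(v * (1 - a), filter = a, method = "recursive")
    v <- as.numeric(v)
  }
  d <- adc$decimation
  n_keep <- (length(v) %/% d) * d
  idx <- seq(1, n_keep, by = d)
  recording(v[idx], fs_hi / d,
            meta = list(decimation = d, fs_hi = fs_hi,
                        anti_alias = adc$anti_alias))
}

#' Simulate a differential LFP recording
#'
#' Runs the full model chain: brain-layer sources ([assemble_sources()]),
#' differential stage with mismatch-dependent artifact leakage
#' ([differential_stage()]), the configured amplifier
#' ([apply_amplifier()]), and ADC decimation ([adc_decimate()]). The
#' returned recording's `meta` captures every parameter and seed used.
#'
#' @param brain A [brain_config()].
#' @param stim A [stim_config()].
#' @param lead A [lead_model()].
#' @param amp An [amplifier_config()].
#' @param adc An [adc_config()].
#' @return A [recording()] at `brain$fs_hi / adc$decimation` Hz.
#' @examples
#' rec <- simulate_recording(brain_config(duration = 5),
#'                           stim_config(amplitude = 6),
#'                           lead_model(), amplifier_config("soft_clip"),
#'                           adc_config())
#' rec
#' @export
simulate_recording <- function(brain = brain_config(),
                               stim = stim_config(),
                               lead = lead_model(),
                               amp = amplifier_config(),
                               adc = adc_config()) {
  src <- assemble_sources(brain, stim)
  dif <- differential_stage(src$x1, src$x3, src$S, src$orm, lead)
  out <- apply_amplifier(dif$samples, amp)
  rec <- adc_decimate(source_signal(out, brain$fs_hi, "dlfp"), adc)
  rec$meta <- c(rec$meta,
                list(stim_amplitude = stim$amplitude, seed = brain$seed,
                     amp_model = amp$model, Z1 = lead$Z1, Z3 = lead$Z3,
                     brain = brain, stim = stim, lead = lead, amp = amp,
                     adc = adc))
  rec
}
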