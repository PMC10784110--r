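test_that("oscillation generator produces an exact, bin-verified sinusoid", {
  osc <- gen_oscillation(15, 2e-3, 4220, 20)
  expect_length(osc$samples, 84400)
  expect_equal(max(abs(osc$samples)), 2e-3, tolerance = 1e-6)
  expect_identical(osc$samples[1], 0)  # zero initial phase

  # dominant spectral component sits at 15 Hz (independent periodogram)
  expect_equal(oracle_peak_freq(osc$samples, 4220), 15, tolerance = 0.1)

  expect_identical(gen_oscillation(15, 0, 4220, 1)$samples, numeric(4220))
  expect_error(gen_oscillation(3000, 1, 4220, 1), "alias")
  expect_error(gen_oscillation(15, 1, -1, 1), "fs")
  expect_error(gen_oscillation(15, 1, 4220, 0), "duration")
})

test_that("pink noise follows the 1/f law and is seed-deterministic", {
  n <- gen_pink_noise(1e-3, 4220, 20, seed = 11)
  expect_length(n$samples, 84400)
  expect_lt(abs(mean(n$samples)), 1e-4)

  # independent seeds decorrelate; the raw correlation of two 1/f series
  # is dominated by their few lowest-frequency components (sd(r) ~ 0.08
  # with a 0.05 Hz fundamental), so independence is asserted on the
  # first-differenced (whitened) series where the test is well powered
  n2 <- gen_pink_noise(1e-3, 4220, 20, seed = 12)
  expect_lt(abs(cor(diff(n$samples), diff(n2$samples))), 0.05)
  expect_lt(abs(cor(n$samples, n2$samples)), 0.3)

  # log-log slope of the full-resolution periodogram ~ -1 over 2-100 Hz
  p <- oracle_periodogram(n$samples, 4220)
  sel <- p$freqs >= 2 & p$freqs <= 100
  slope <- coef(lm(log10(p$power[sel]) ~ log10(p$freqs[sel])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.2)

  # absolute level: PSD at f is strength^2 / f (one-sided)
  sel10 <- p$freqs >= 5 & p$freqs <= 20
  at10 <- mean(2 * p$power[sel10] * p$freqs[sel10])
  expect_equal(at10, 1e-6, tolerance = 0.3)

  expect_identical(gen_pink_noise(0, 422, 1)$samples, numeric(422))
  expect_identical(gen_pink_noise(1e-3, 422, 2, seed = 5)$samples,
                   gen_pink_noise(1e-3, 422, 2, seed = 5)$samples)
})

test_that("pink noise generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_pink_noise(1e-3, 422, 1, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("stimulation artifact contains exactly the retained harmonics", {
  stim <- stim_config(amplitude = 2, n_harmonics = 6)
  s <- gen_stim_artifact(stim, 4220, 20)
  p <- oracle_periodogram(s$samples, 4220)
  # census: every bin more than 40 dB below the maximum must be noise;
  # surviving bins must all lie within 0.1 Hz of a harmonic of 130
  loud <- p$freqs[p$power > max(p$power) * 1e-4]
  nearest_harm <- round(loud / 130) * 130
  expect_true(all(abs(loud - nearest_harm) < 0.1))
  expect_setequal(unique(round(nearest_harm)), c(130, 260, 390, 520, 650, 780))

  # linear amplitude scaling: 8 V output is elementwise 4x the 2 V output
  s8 <- gen_stim_artifact(stim_config(amplitude = 8), 4220, 2)
  s2 <- gen_stim_artifact(stim_config(amplitude = 2), 4220, 2)
  expect_equal(s8$samples, 4 * s2$samples, tolerance = 1e-12)

  expect_identical(gen_stim_artifact(stim_config(amplitude = 0), 4220, 1)$samples,
                   numeric(4220))
  # harmonics above Nyquist must raise, not be dropped
  expect_error(
    gen_stim_artifact(stim_config(amplitude = 1, n_harmonics = 17), 4220, 1),
    "not representable")
})

test_that("harmonic weighting rules are normalised and selectable", {
  w_pulse <- harmonic_weights(stim_config(amplitude = 1))
  expect_identical(w_pulse[1], 1)
  # biphasic 90 us pulse weights at 130 Hz rise ~ linearly over k = 1..6
  expect_true(all(diff(w_pulse) > 0))
  expect_equal(w_pulse,
               sin(pi * 1:6 * 130 * 90e-6)^2 / (1:6) /
                 (sin(pi * 130 * 90e-6)^2),
               tolerance = 1e-12)

  w_inv <- harmonic_weights(stim_config(harmonic_decay = "inv_k"))
  expect_equal(w_inv, 1 / (1:6))
})

test_that("stimulation scale can be set orders of magnitude above oscillations", {
  osc_amp <- 2e-3
  stim <- stim_config(amplitude = 1e6 * osc_amp)
  s <- gen_stim_artifact(stim, 4220, 2)
  osc <- gen_oscillation(15, osc_amp, 4220, 2)
  w <- harmonic_weights(stim)
  expected_ratio <- 1e6 * sqrt(sum(w^2))  # RMS of a sum of orthogonal sines
  ratio <- sqrt(mean(s$samples^2)) / sqrt(mean(osc$samples^2))
  expect_equal(ratio, expected_ratio, tolerance = 0.01)
})

test_that("ORM tone lands on its exact Welch bin after the full pipeline", {
  o <- gen_orm(4220, 20, 1e-3)
  expect_equal(oracle_peak_freq(o$samples, 4220), 105.5, tolerance = 0.1)
  expect_identical(gen_orm(4220, 1, 0)$samples, numeric(4220))

  # decimated grid arithmetic: 422 * 256 / 1024 = 105.5 exactly
  psd <- welch_logpsd(adc_decimate(o, adc_config()))
  expect_identical(psd$freqs[257], 105.5)
  expect_equal(psd$freqs[which.max(psd$values)], 105.5)
})

test_that("assembled sources separate the oscillation into x1 only", {
  cfg <- brain_config(duration = 20, seed = 7)
  src <- assemble_sources(cfg, stim_config(amplitude = 2))
  expect_named(src, c("x1", "x3", "S", "orm"))

  # x1 carries a 15 Hz peak; x3 must not (< 2x local background in power)
  peak_vs_background <- function(x) {
    p <- oracle_periodogram(x, 4220)
    at <- abs(p$freqs - 15) <= 0.5
    local <- p$freqs > 10 & p$freqs < 20 & abs(p$freqs - 15) > 2
    mean(p$power[at]) / median(p$power[local])
  }
  expect_gt(peak_vs_background(src$x1$samples), 5)
  expect_lt(peak_vs_background(src$x3$samples), 2)

  # zero-amplitude config produces zero neural sources
  z <- assemble_sources(
    brain_config(duration = 1, osc_amplitude = 0, pink_strength = 0),
    stim_config())
  expect_identical(z$x1$samples, numeric(4220))
  expect_identical(z$x3$samples, numeric(4220))

  # byte-identical determinism
  src2 <- assemble_sources(cfg, stim_config(amplitude = 2))
  expect_identical(src$x1$samples, src2$x1$samples)
  expect_identical(src$x3$samples, src2$x3$samples)
})
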