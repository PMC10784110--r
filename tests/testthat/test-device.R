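test_that("leakage law reproduces the device calibration point and clamps", {
  # matched electrodes reject everything
  expect_identical(leakage_amplitude(8, lead_model(Z1 = 500, Z3 = 500)), 0)
  # calibration: 5 V at 1000 ohm mismatch with Z_b = 1e4 leaks 0.5 V (10%)
  expect_identical(
    leakage_amplitude(5, lead_model(Z1 = 1000, Z3 = 2000, Z_b = 1e4)), 0.5)
  # mismatch at/above the channel impedance saturates at full amplitude
  expect_identical(
    leakage_amplitude(3, lead_model(Z1 = 0, Z3 = 2e4, Z_b = 1e4)), 3)
  expect_error(lead_model(Z1 = -5), "Z1")
})

test_that("differential stage cancels common mode and scales leakage", {
  fs <- 4220
  x <- gen_pink_noise(1e-3, fs, 2, seed = 3)
  zero <- source_signal(numeric(length(x$samples)), fs, "orm")
  stim0 <- gen_stim_artifact(stim_config(amplitude = 0), fs, 2)

  # identical electrode signals, no leakage, no ORM -> silence
  out <- differential_stage(x, x, stim0, zero, lead_model())
  expect_identical(out$samples, numeric(length(x$samples)))

  # matched impedances: stimulation leaves no 130 Hz trace
  src <- assemble_sources(brain_config(duration = 20),
                          stim_config(amplitude = 8))
  matched <- differential_stage(src$x1, src$x3, src$S, src$orm,
                                lead_model(Z1 = 1500, Z3 = 1500))
  p <- oracle_periodogram(matched$samples, fs)
  at130 <- which.min(abs(p$freqs - 130))
  local <- abs(p$freqs - 130) < 10 & abs(p$freqs - 130) > 2
  expect_lt(p$power[at130] / median(p$power[local]), 2)

  # leaked artifact peak equals the leakage amplitude, and dwarfs the
  # neural oscillation at default study settings (6 V, 1000 ohm mismatch)
  lead <- lead_model(Z1 = 1000, Z3 = 2000)
  src6 <- assemble_sources(brain_config(duration = 2),
                           stim_config(amplitude = 6))
  mixed <- differential_stage(src6$x1, src6$x3, src6$S, src6$orm, lead)
  neural <- src6$x1$samples - src6$x3$samples
  leaked <- mixed$samples - neural - src6$orm$samples
  expect_equal(max(abs(leaked)), leakage_amplitude(6, lead),
               tolerance = 1e-10)
  osc_rms <- 2e-3 / sqrt(2)
  expect_gt(sqrt(mean(leaked^2)) / osc_rms, 100)

  # length mismatch is an error
  short <- gen_pink_noise(1e-3, fs, 1, seed = 4)
  expect_error(differential_stage(x, short, stim0, zero, lead_model()),
               "length")
})

test_that("soft clip is the exact tanh law with its limits", {
  amp <- amplifier_config("soft_clip", g1 = 1, g2 = 1)
  expect_identical(soft_clip(0, amp), 0)
  expect_equal(soft_clip(0.5, amp), tanh(0.5), tolerance = 1e-12)
  expect_equal(soft_clip(0.5, amp), 0.462117, tolerance = 1e-6)
  # odd symmetry and saturation bounds (tanh reaches g2 only in the
  # floating-point limit)
  v <- seq(-50, 50, length.out = 1001)
  a2 <- amplifier_config("soft_clip", g1 = 2, g2 = 3)
  expect_equal(soft_clip(v, a2), -soft_clip(-v, a2), tolerance = 1e-12)
  expect_true(all(abs(soft_clip(v, a2)) <= 3))
  expect_true(all(abs(soft_clip(v[abs(v) <= 5], a2)) < 3))
  expect_equal(soft_clip(1e6, a2), 3, tolerance = 1e-12)
  expect_error(soft_clip(1, amplifier_config("linear")), "soft_clip")
})

test_that("small signals pass the soft clip as if the amp were linear", {
  v <- runif(1000, -0.009, 0.009)
  amp <- amplifier_config("soft_clip", g1 = 1, g2 = 1)
  lin <- amplifier_config("linear", g1 = 1, g2 = 1)
  rel <- abs(soft_clip(v, amp) - apply_amplifier(v, lin)) / abs(v)
  expect_lt(max(rel), 1e-4)  # within 0.01% for |g1 v| < 0.01
})

test_that("hard clip is linear below threshold and clamps above", {
  amp <- amplifier_config("hard_clip", clip_level = 1)
  v <- seq(-0.99, 0.99, length.out = 201)
  expect_identical(hard_clip(v, amp), v)
  expect_identical(hard_clip(2, amp), 1)
  expect_identical(hard_clip(-5, amp), -1)

  # driving a sinusoid past the clip generates odd harmonics only
  fs <- 4220
  t <- (0:(fs * 2 - 1)) / fs
  clipped <- hard_clip(3 * sin(2 * pi * 100 * t), amp)
  p <- oracle_periodogram(clipped, fs)
  at <- function(f) p$power[which.min(abs(p$freqs - f))]
  expect_gt(at(300) / at(200), 100)  # 3rd harmonic >> 2nd
  expect_gt(at(500) / at(400), 100)  # 5th harmonic >> 4th
})

test_that("ADC decimation keeps every d-th sample and aliases tones", {
  x <- source_signal(rnorm(84400), 4220, "x1")
  rec <- adc_decimate(x, adc_config(decimation = 10))
  expect_length(rec$samples, 8440)
  expect_identical(rec$fs, 422)
  expect_identical(rec$samples, x$samples[seq(1, 84400, by = 10)])

  # identity decimation
  rec1 <- adc_decimate(x, adc_config(decimation = 1))
  expect_identical(rec1$samples, x$samples)

  # a 390 Hz tone at 4220 Hz appears at 32 Hz after 10x decimation
  tone <- gen_oscillation(390, 1, 4220, 20)
  dec <- adc_decimate(tone, adc_config())
  expect_equal(oracle_peak_freq(dec$samples, 422), 32, tolerance = 0.1)

  # trailing remainder is truncated
  odd <- source_signal(rnorm(1005), 4220, "x1")
  expect_length(adc_decimate(odd, adc_config())$samples, 100)
  expect_error(adc_config(decimation = 0), "decimation")
})

test_that("anti-alias option suppresses the aliased tone", {
  tone <- gen_oscillation(390, 1, 4220, 20)
  plain <- adc_decimate(tone, adc_config())
  filt <- adc_decimate(tone, adc_config(anti_alias = TRUE))
  p_plain <- welch_psd(plain)
  p_filt <- welch_psd(filt)
  at32 <- which.min(abs(p_plain$freqs - 32))
  expect_lt(p_filt$power[at32], p_plain$power[at32] / 10)
})

test_that("full simulation chain is deterministic and traceable", {
  r1 <- simulate_recording(brain_config(duration = 2, seed = 5),
                           stim_config(amplitude = 4))
  r2 <- simulate_recording(brain_config(duration = 2, seed = 5),
                           stim_config(amplitude = 4))
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$fs, 422)
  expect_identical(r1$meta$stim_amplitude, 4)
  expect_identical(r1$meta$amp_model, "soft_clip")
  expect_identical(r1$meta$seed, 5L)
  expect_identical(r1$meta$Z1, 1000)
  expect_s3_class(r1$meta$brain, "brain_config")
})

test_that("a stimulation-free recording contains only the modelled tones", {
  psd <- psd_of(rec_quiet())
  pk <- find_peaks(psd, c(15, 105.5), tol_bins = 1)
  expect_true(all(pk$found))
  # none of the artifact frequencies are present without stimulation
  pk_art <- find_peaks(psd, c(32, 64, 66, 98, 130, 162, 194), tol_bins = 1)
  expect_false(any(pk_art$found))
})

test_that("matched electrodes make stimulation spectrally invisible", {
  rec_stim <- simulate_recording(brain_config(duration = 20, seed = 2),
                                 stim_config(amplitude = 8),
                                 lead_model(Z1 = 1200, Z3 = 1200),
                                 amplifier_config("soft_clip"))
  rec_off <- simulate_recording(brain_config(duration = 20, seed = 2),
                                stim_config(amplitude = 0),
                                lead_model(Z1 = 1200, Z3 = 1200),
                                amplifier_config("soft_clip"))
  p_stim <- welch_logpsd(rec_stim)
  p_off <- welch_logpsd(rec_off)
  for (b in names(standard_bands()$windows)) {
    expect_equal(band_power(p_stim, standard_bands(), b, "median"),
                 band_power(p_off, standard_bands(), b, "median"),
                 tolerance = 0.5)
  }
})

test_that("compression-specific 66 Hz power appears only with a nonlinear amp", {
  # nonlinearity gate: linear amp leaves the IMH bin at the noise floor
  psd_soft <- psd_of(rec_soft6())
  psd_lin <- psd_of(rec_lin6())
  expect_true(find_peaks(psd_soft, 66)$found)
  expect_false(find_peaks(psd_lin, 66)$found)

  # 66 Hz IMH power grows with stimulation amplitude (2-8 V)
  at66 <- function(v) {
    rec <- simulate_recording(brain_config(duration = 20),
                              stim_config(amplitude = v),
                              lead_model(Z1 = 1000, Z3 = 2000),
                              amplifier_config("soft_clip"))
    p <- welch_logpsd(rec)
    max(p$values[abs(p$freqs - 66) < 0.5])
  }
  pow <- vapply(c(2, 4, 6, 8), at66, numeric(1))
  expect_true(all(diff(pow) > 0))
})
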