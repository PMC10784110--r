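# Shared simulated fixtures, built once per test run. The 20 s runs
# reproduce the default study conditions (130 Hz stimulation, 1000 ohm
# mismatch, 422 Hz output rate); shorter runs are used where full length
# adds nothing.

fix_env <- new.env()

fixture_recording <- function(key, amplitude, model, duration = 20,
                              Z3 = 2000, seed = 1L) {
  if (is.null(fix_env[[key]])) {
    fix_env[[key]] <- simulate_recording(
      brain_config(duration = duration, seed = seed),
      stim_config(amplitude = amplitude),
      lead_model(Z1 = 1000, Z3 = Z3),
      amplifier_config(model),
      adc_config())
  }
  fix_env[[key]]
}

rec_soft6 <- function() fixture_recording("soft6", 6, "soft_clip")
rec_lin6 <- function() fixture_recording("lin6", 6, "linear")
rec_quiet <- function() fixture_recording("quiet", 0, "linear")
rec_soft8 <- function() fixture_recording("soft8", 8, "soft_clip")

psd_of <- function(rec) {
  key <- paste0("psd_", substr(digest_samples(rec), 1, 12))
  if (is.null(fix_env[[key]])) fix_env[[key]] <- welch_logpsd(rec)
  fix_env[[key]]
}

digest_samples <- function(rec) {
  paste(format(sum(rec$samples^2), digits = 15),
        length(rec$samples), rec$fs, sep = "_")
}
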