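# Default-protocol voltage sweep (0,2..8 V, soft clip, 1000 ohm mismatch,
# 20 s paired-noise conditions), shared by the sweep-based tests.
fix_sweep <- function() {
  if (is.null(fix_env$sweep)) fix_env$sweep <- run_sweep(sweep_protocol())
  fix_env$sweep
}

fix_sweep_psds <- function() {
  if (is.null(fix_env$sweep_psds))
    fix_env$sweep_psds <- lapply(fix_sweep(), welch_logpsd)
  fix_env$sweep_psds
}
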