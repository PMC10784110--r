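# Experiment fixtures: the acute voltage-sweep protocol and the chronic
# (weekly) impedance-mismatch series.

#' Voltage sweep protocol
#'
#' Settings for the acute sweep experiment: stimulation is stepped through
#' a list of voltages with otherwise fixed parameters, one recording per
#' condition. The clinical protocol delivers each condition for 1 min with
#' washout in between; simulated sweeps default to 20 s conditions and no
#' washout.
#'
#' By default the same noise seed is used for every voltage (a paired
#' design: across-voltage differences then reflect stimulation effects
#' only, not noise realisation). Set `paired_seeds = FALSE` to draw
#' independent backgrounds per condition (seed incremented per voltage).
#'
#' @param voltages Stimulation voltages, V (default `c(0, 2:8)`).
#' @param on_duration Seconds per condition (default 20).
#' @param washout Washout seconds between conditions (default 0; recorded
#'   in the protocol but not simulated).
#' @param brain,stim,lead,amp,adc Layer configurations; `stim$amplitude`
#'   is overridden per condition.
#' @param paired_seeds Reuse the same noise seed across voltages
#'   (default `TRUE`).
#' @return An object of class `sweep_protocol`.
#' @seealso [run_sweep()]
#' @export
sweep_protocol <- function(voltages = c(0, 2:8), on_duration = 20,
                           washout = 0,
                           brain = brain_config(), stim = stim_config(),
                           lead = lead_model(), amp = amplifier_config(),
                           adc = adc_config(), paired_seeds = TRUE) {
  if (!is.numeric(voltages) || length(voltages) == 0 || any(voltages < 0))
    stop_config("voltages must be a non-empty non-negative numeric vector")
  check_scalar(on_duration, "on_duration", 0, strict_lower = TRUE)
  check_scalar(washout, "washout", 0)
  stopifnot(inherits(brain, "brain_config"), inherits(stim, "stim_config"),
            inherits(lead, "lead_model"), inherits(amp, "amplifier_config"),
            inherits(adc, "adc_config"),
            is.logical(paired_seeds), length(paired_seeds) == 1L)
  brain$duration <- on_duration
  structure(list(voltages = as.numeric(voltages), on_duration = on_duration,
                 washout = washout, brain = brain, stim = stim, lead = lead,
                 amp = amp, adc = adc, paired_seeds = paired_seeds),
            class = "sweep_protocol")
}

#' Run a voltage sweep
#'
#' Simulates one recording per protocol voltage.
#'
#' @param protocol A [sweep_protocol()].
#' @return A named list of [recording()] objects (names `"0V"`, `"2V"`, ...).
#' @examples
#' recs <- run_sweep(sweep_protocol(voltages = c(0, 6), on_duration = 5))
#' names(recs)
#' @export
run_sweep <- function(protocol) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  recs <- lapply(seq_along(protocol$voltages), function(i) {
    stim <- protocol$stim
    stim$amplitude <- protocol$voltages[i]
    brain <- protocol$brain
    if (!protocol$paired_seeds)
      brain$seed <- brain$seed + 2L * (i - 1L)  # x1/x3 use seed, seed + 1
    simulate_recording(brain, stim, protocol$lead, protocol$amp,
                       protocol$adc)
  })
  names(recs) <- paste0(protocol$voltages, "V")
  recs
}

#' Generate a chronic impedance-mismatch series
#'
#' Emulates the two-phase dynamics of weekly electrode impedances after
#' implantation: a variable phase with large week-to-week mismatch changes
#' followed by a stable phase. The mismatch follows a bounded random walk
#' (default steps: sd 150 ohm/week before `phase_change_week`, 20 ohm/week
#' after, clamped to the observed 0-600 ohm range), and one recording is
#' simulated per week at fixed stimulation settings with the week's lead
#' mismatch and a week-specific noise seed.
#'
#' @param weeks Number of weeks (>= 1).
#' @param phase_change_week Last week of the variable phase (default 10);
#'   must be below `weeks` (ignored when `weeks == 1`).
#' @param seed Base RNG seed: the walk uses `seed`, week w's recording
#'   noise uses `seed + 10 * w`.
#' @param sd_variable,sd_stable Random-walk step standard deviations,
#'   ohm/week.
#' @param mismatch_range Clamp for the mismatch, ohms.
#' @param z_base Impedance of the reference electrode Z1, ohms.
#' @param stim,amp,adc,brain Fixed per-week simulation settings
#'   (`brain$seed` is overridden per week).
#' @return A `chronic_series` object: list with `table` (data frame:
#'   `week`, `Z1`, `Z3`, `mismatch`) and `recordings` (list, one per week).
#' @export
gen_chronic_series <- function(weeks, phase_change_week = 10L, seed = 1L,
                               sd_variable = 150, sd_stable = 20,
                               mismatch_range = c(0, 600), z_base = 1000,
                               stim = stim_config(amplitude = 6),
                               amp = amplifier_config(),
                               adc = adc_config(),
                               brain = brain_config()) {
  check_scalar(weeks, "weeks", 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  if (weeks > 1) {
    check_scalar(phase_change_week, "phase_change_week", 1,
                 integerish = TRUE)
    if (phase_change_week >= weeks)
      stop_config("phase_change_week (%d) must be below weeks (%d)",
                  phase_change_week, weeks)
  }
  mism <- with_seed(seed, {
    m <- numeric(weeks)
    m[1] <- stats::runif(1, mismatch_range[1], mismatch_range[2])
    if (weeks > 1) for (w in 2:weeks) {
      sdw <- if (w <= phase_change_week) sd_variable else sd_stable
      m[w] <- min(max(m[w - 1] + stats::rnorm(1, sd = sdw),
                      mismatch_range[1]), mismatch_range[2])
    }
    m
  })
  recs <- lapply(seq_len(weeks), function(w) {
    b <- brain
    b$seed <- as.integer(seed + 10L * w)
    simulate_recording(b, stim, lead_model(Z1 = z_base, Z3 = z_base + mism[w]),
                       amp, adc)
  })
  structure(
    list(table = data.frame(week = seq_len(weeks), Z1 = z_base,
                            Z3 = z_base + mism, mismatch = mism),
         recordings = recs,
         phase_change_week = if (weeks > 1) as.integer(phase_change_week)
           else NA_integer_,
         seed = as.integer(seed)),
    class = "chronic_series")
}

#' @export
print.chronic_series <- function(x, ...) {
  cat(sprintf(
    "<chronic_series> %d weeks (phase change after week %s), mismatch %g-%g ohm\n",
    nrow(x$table), x$phase_change_week, min(x$table$mismatch),
    max(x$table$mismatch)))
  invisible(x)
}
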