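# Quality diagnostics: gain compression ratio, over-range-marker power,
# impedance-mismatch bookkeeping.

#' Gain compression ratio (GCr)
#'
#' The log-ratio of power at the aliased-shaping-harmonic frequency versus
#' the intermodulation-harmonic frequency, computed on the raw log-PSD:
#'
#'   `GCr = ASH_dB - IMH_dB`
#'
#' Sign convention: since the ASH exists even without any compression
#' while the IMH is created by the nonlinearity, larger GCr means *less*
#' compression (the IMH sits closer to the noise floor). Power at each
#' target is taken as the maximum dB value within `bandwidth_bins` bins of
#' the nearest grid bin. Being a ratio, GCr is invariant to any constant
#' dB offset on the whole spectrum (e.g. unknown absolute gain).
#'
#' @param psd A `log_psd`.
#' @param cfg A [gcr_config()] (defaults 64 Hz vs 66 Hz).
#' @return GCr in dB.
#' @export
compute_gcr <- function(psd, cfg = gcr_config()) {
  stopifnot(inherits(psd, "log_psd"), inherits(cfg, "gcr_config"))
  nyq <- max(psd$freqs)
  if (cfg$f_ash > nyq || cfg$f_imh > nyq)
    stop_config("GCr frequencies must lie within the PSD grid (max %g Hz)",
                nyq)
  peak_db <- function(f) {
    ib <- nearest_bin(psd, f)
    idx <- max(1L, ib - cfg$bandwidth_bins):
      min(length(psd$freqs), ib + cfg$bandwidth_bins)
    max(psd$values[idx])
  }
  peak_db(cfg$f_ash) - peak_db(cfg$f_imh)
}

#' Over-range-marker power
#'
#' Power at the ORM bin plus a discernibility flag. The marker is injected
#' at constant amplitude, so its measured power should be constant; a drop
#' indicates gain compression and a peak that is no longer discernible
#' above its local background indicates saturation.
#'
#' @param psd A `log_psd`.
#' @param orm_freq Marker frequency, Hz (default 105.5).
#' @param threshold_db Prominence threshold for discernibility (default 6).
#' @return A list with `power_db` (dB at the nearest bin) and
#'   `discernible` (logical).
#' @export
orm_power <- function(psd, orm_freq = 105.5, threshold_db = 6) {
  stopifnot(inherits(psd, "log_psd"))
  if (orm_freq > max(psd$freqs))
    stop_config("ORM frequency %g Hz is outside the PSD grid", orm_freq)
  if (min(diff(psd$freqs)) > 2)
    stop_config("PSD grid too coarse to resolve the ORM tone")
  pk <- find_peaks(psd, orm_freq, tol_bins = 1L, threshold_db = threshold_db)
  list(power_db = psd$values[nearest_bin(psd, orm_freq)],
       discernible = pk$found[1])
}

#' Impedance mismatch
#'
#' Absolute difference of the two recording electrodes' impedances.
#'
#' @param z_a,z_b Electrode impedances in ohms (non-negative; vectorised).
#' @return `|z_a - z_b|` in ohms.
#' @examples
#' impedance_mismatch(800, 1300)  # 500
#' @export
impedance_mismatch <- function(z_a, z_b) {
  if (any(z_a < 0) || any(z_b < 0))
    stop_config("impedances must be non-negative")
  abs(z_a - z_b)
}

#' Batch diagnostics for a set of recordings
#'
#' Computes GCr and ORM power for each recording, as emitted by the CLI's
#' batch mode.
#'
#' @param recs List of [recording()] objects (optionally named).
#' @param gcr A [gcr_config()].
#' @param welch A [welch_config()].
#' @param orm_freq Marker frequency, Hz.
#' @return Data frame with columns `recording_id`, `gcr_db`, `orm_db`,
#'   `orm_discernible`.
#' @export
diagnostics_table <- function(recs, gcr = gcr_config(),
                              welch = welch_config(), orm_freq = 105.5) {
  stopifnot(is.list(recs))
  ids <- names(recs)
  if (is.null(ids)) ids <- as.character(seq_along(recs))
  rows <- lapply(seq_along(recs), function(i) {
    psd <- welch_logpsd(recs[[i]], welch)
    o <- orm_power(psd, orm_freq)
    data.frame(recording_id = ids[i], gcr_db = compute_gcr(psd, gcr),
               orm_db = o$power_db, orm_discernible = o$discernible)
  })
  do.call(rbind, rows)
}
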