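# Compression-mitigation pipeline: polynomial baseline removal on the
# log-PSD, artifact-avoiding adjusted bands, median aggregation.

#' Fit and remove a polynomial spectral baseline
#'
#' Least-squares polynomial fit (in frequency, Hz, on a linear axis by
#' default) to the log-PSD over the configured fit range, capturing the
#' broad-spectrum shape -- the 1/f background and any compression-driven
#' slope flattening. The baseline is evaluated on the full grid and
#' subtracted; narrowband structure (oscillations and artifacts) survives
#' in the residual. Artifact bins are deliberately not masked during the
#' fit: the band-window and median steps of the pipeline are responsible
#' for narrowband robustness.
#'
#' @param psd A `log_psd`.
#' @param cfg A [mitigation_config()].
#' @return A `corrected_psd` object: list with `freqs`, `residual_db`,
#'   `baseline_db`, `coefficients` (ascending powers, length
#'   `poly_order + 1`), `fit_range`, and the input `psd`.
#' @export
fit_baseline <- function(psd, cfg = mitigation_config()) {
  stopifnot(inherits(psd, "log_psd"), inherits(cfg, "mitigation_config"))
  in_range <- psd$freqs >= cfg$fit_range[1] & psd$freqs <= cfg$fit_range[2] &
    psd$freqs > 0
  if (sum(in_range) < cfg$poly_order + 1)
    stop_config("only %d bins in fit range; need at least %d for order %d",
                sum(in_range), cfg$poly_order + 1, cfg$poly_order)
  fx <- if (cfg$log_freq) log10(psd$freqs[in_range]) else psd$freqs[in_range]
  y <- psd$values[in_range]
  # fit on a centred/scaled basis (well-conditioned even for Hz^4 terms),
  # then convert the coefficients back to plain powers of frequency
  ctr <- mean(range(fx))
  scl <- max(diff(range(fx)) / 2, .Machine$double.eps)
  z <- (fx - ctr) / scl
  b <- qr.coef(qr(outer(z, 0:cfg$poly_order, `^`)), y)
  coefs <- poly_rebase(b, ctr, scl)
  fx_all <- if (cfg$log_freq) {
    fa <- psd$freqs
    fa[fa <= 0] <- min(psd$freqs[psd$freqs > 0])  # guard DC bin
    log10(fa)
  } else psd$freqs
  z_all <- (fx_all - ctr) / scl
  baseline <- as.vector(outer(z_all, 0:cfg$poly_order, `^`) %*% b)
  structure(
    list(freqs = psd$freqs, residual_db = psd$values - baseline,
         baseline_db = baseline, coefficients = unname(coefs),
         fit_range = cfg$fit_range, psd = psd),
    class = "corrected_psd")
}

#' @export
print.corrected_psd <- function(x, ...) {
  cat(sprintf(
    "<corrected_psd> order-%d baseline over %g-%g Hz, residual sd %.3g dB\n",
    length(x$coefficients) - 1, x$fit_range[1], x$fit_range[2],
    stats::sd(x$residual_db)))
  invisible(x)
}

# Re-express sum_j b_j ((x - ctr)/scl)^j as coefficients of plain x^k,
# by expanding the binomials.
poly_rebase <- function(b, ctr, scl) {
  ord <- length(b) - 1
  out <- numeric(ord + 1)
  for (j in 0:ord) {
    # b_j / scl^j * (x - ctr)^j
    for (k in 0:j) {
      out[k + 1] <- out[k + 1] +
        b[j + 1] / scl^j * choose(j, k) * (-ctr)^(j - k)
    }
  }
  out
}

# residual of a corrected PSD, repackaged as a log_psd for band analysis
residual_psd <- function(corrected) {
  out <- corrected$psd
  out$values <- corrected$residual_db
  out
}

#' Run the mitigation pipeline
#'
#' Applies, in order: (1) Welch log-PSD estimation when given a recording,
#' (2) polynomial baseline fit and subtraction ([fit_baseline()]),
#' (3) band-power extraction with the artifact-avoiding adjusted scheme,
#' (4) median aggregation across the bins of each band. Returns one row
#' per band of corrected band power.
#'
#' @param x A [recording()] or a `log_psd`.
#' @param cfg A [mitigation_config()].
#' @param welch A [welch_config()] used when `x` is a recording.
#' @return A data frame as from [band_power_table()], computed on the
#'   detrended spectrum.
#' @export
mitigate <- function(x, cfg = mitigation_config(), welch = welch_config()) {
  psd <- if (inherits(x, "recording")) welch_logpsd(x, welch)
    else if (inherits(x, "log_psd")) x
    else stop_config("x must be a recording or a log_psd")
  corrected <- fit_baseline(psd, cfg)
  band_power_table(residual_psd(corrected), cfg$scheme, cfg$aggregator)
}

#' Compare band-power conventions side by side
#'
#' The 2 x 2 grid of band-power tables -- standard vs adjusted band scheme,
#' mean vs median aggregation -- computed on the raw (undetrended)
#' log-PSD of one recording, for side-by-side reporting of how much the
#' convention alone changes measured oscillatory power.
#'
#' @param rec A [recording()] or `log_psd`.
#' @param welch A [welch_config()] used when `rec` is a recording.
#' @return A data frame with one row per (scheme, aggregator, band).
#' @export
compare_schemes <- function(rec, welch = welch_config()) {
  psd <- if (inherits(rec, "recording")) welch_logpsd(rec, welch)
    else if (inherits(rec, "log_psd")) rec
    else stop_config("rec must be a recording or a log_psd")
  grids <- expand.grid(scheme = c("standard", "adjusted"),
                       aggregator = c("mean", "median"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grids)), function(i) {
    sch <- if (grids$scheme[i] == "standard") standard_bands()
      else adjusted_bands()
    band_power_table(psd, sch, grids$aggregator[i])
  })
  do.call(rbind, out)
}
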