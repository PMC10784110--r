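# File I/O: recordings and spectra as plain-text CSV with a commented
# metadata header; band tables as TSV; simulation configs as YAML/JSON.

scalar_meta_fields <- c("fs", "seed", "stim_amplitude", "amp_model",
                        "Z1", "Z3", "decimation", "fs_hi", "label")

#' Write a recording (or source signal) to CSV
#'
#' Two-column CSV (`time_s,value`) preceded by `# key: value` comment
#' lines carrying the sampling rate and scalar metadata (seed, stimulation
#' amplitude, amplifier model, electrode impedances), so the file
#' round-trips losslessly through [read_recording()].
#'
#' @param rec A [recording()] or [source_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording") || inherits(rec, "source_signal"))
  meta <- rec$meta
  meta$fs <- rec$fs
  if (inherits(rec, "source_signal")) meta$label <- rec$label
  keep <- intersect(scalar_meta_fields, names(meta))
  hdr <- vapply(keep, function(k) {
    v <- meta[[k]]
    sprintf("# %s: %s", k,
            if (is.numeric(v)) format(v, digits = 17) else as.character(v))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,value", con)
  df <- as.data.frame(rec)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

parse_meta_header <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[trimws(m[2])]] <- if (is.na(val)) trimws(m[3]) else val
    }
  }
  meta
}

#' Read a recording from CSV
#'
#' Inverse of [write_recording()]. The file must contain a
#' `time_s,value` header row; `# fs:` metadata is required (there is no
#' way to reconstruct the sampling grid without it).
#'
#' @param path Input file path.
#' @return A [recording()] with the stored metadata in `meta`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  lines <- readLines(path)
  meta <- parse_meta_header(lines)
  body_start <- which(!grepl("^#", lines))[1]
  if (is.na(body_start) || !grepl("^time_s\\s*,\\s*value", lines[body_start]))
    stop_config("%s: missing 'time_s,value' header row (line %d)",
                path, ifelse(is.na(body_start), length(lines), body_start))
  if (is.null(meta$fs))
    stop_config("%s: missing required '# fs:' metadata", path)
  body <- lines[(body_start + 1):length(lines)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop_config("%s: malformed row at line %d", path, body_start + bad[1])
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (any(is.na(vals)))
    stop_config("%s: non-numeric value at line %d", path,
                body_start + which(is.na(vals))[1])
  fs <- meta$fs
  meta$fs <- NULL
  recording(vals, fs, meta = meta)
}

#' Write / read a log-PSD as CSV
#'
#' Columns `freq_hz,power_db`.
#'
#' @param psd A `log_psd`.
#' @param path File path.
#' @return `path` (write) or a `log_psd` (read).
#' @export
write_psd <- function(psd, path) {
  stopifnot(inherits(psd, "log_psd"))
  utils::write.csv(data.frame(freq_hz = psd$freqs, power_db = psd$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psd
#' @export
read_psd <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("freq_hz", "power_db") %in% names(df)))
    stop_config("%s: expected columns freq_hz, power_db", path)
  log_psd(df$freq_hz, df$power_db)
}

#' Write a band-power table as TSV
#'
#' @param tbl A data frame from [band_power_table()], [mitigate()] or
#'   [compare_schemes()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_band_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration file
#'
#' Builds the five layer configurations from a YAML or JSON file whose
#' top-level sections `brain`, `stim`, `lead`, `amp`, `adc` mirror the
#' arguments of [brain_config()], [stim_config()], [lead_model()],
#' [amplifier_config()] and [adc_config()]. Missing sections or fields
#' fall back to the documented defaults; unknown fields are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of config objects
#'   (`brain`, `stim`, `lead`, `amp`, `adc`).
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop_config("config must be .yaml/.yml or .json: %s", path)
  if (is.null(raw)) raw <- list()
  build <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    known <- names(formals(ctor))
    unknown <- setdiff(names(args), known)
    if (length(unknown))
      stop_config("unknown field '%s' in config section '%s'",
                  unknown[1], section)
    do.call(ctor, args)
  }
  list(brain = build("brain", brain_config),
       stim = build("stim", stim_config),
       lead = build("lead", lead_model),
       amp = build("amp", amplifier_config),
       adc = build("adc", adc_config))
}
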