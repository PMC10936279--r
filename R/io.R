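FORMAT_VERSION <- 1L

#' Write and read RF series in the package's plain-text container
#'
#' An RF series is stored as two files under a common stem: `<stem>.json`
#' holding the acquisition attributes (`center_frequency_hz`,
#' `sample_rate_hz`, `prf_hz`, `speed_of_sound_mps`, `gate_upper_mm`,
#' `gate_lower_mm`, `start_time_s`, matrix dimensions, format version) and
#' `<stem>.csv` holding the sample matrix (depth sample x pulse, no
#' header). Reading verifies the format version and the stored dimensions
#' against the actual CSV, so truncated files fail loudly instead of
#' loading partially.
#'
#' @param x An [rf_series()].
#' @param stem File path without extension.
#' @return `write_rf_series()` the stem, invisibly; `read_rf_series()` an
#'   [rf_series()].
#' @export
write_rf_series <- function(x, stem) {
  stopifnot(inherits(x, "rf_series"))
  meta <- list(
    format = "twitchtdi-rf",
    format_version = FORMAT_VERSION,
    center_frequency_hz = x$params$center_frequency,
    sample_rate_hz = x$params$sample_rate,
    prf_hz = x$params$prf,
    speed_of_sound_mps = x$params$speed_of_sound,
    gate_upper_mm = x$params$gate_upper,
    gate_lower_mm = x$params$gate_lower,
    n_depth_samples = nrow(x$samples),
    n_pulses = ncol(x$samples),
    start_time_s = x$start_time
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(x$samples, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' @rdname write_rf_series
#' @export
read_rf_series <- function(stem) {
  meta_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, ".csv")
  if (!file.exists(meta_path) || !file.exists(csv_path)) {
    abort(sprintf("no RF container at stem `%s`.", stem),
          class = "twitchtdi_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "twitchtdi-rf")) {
    abort("not a twitchtdi RF container.", class = "twitchtdi_io_error")
  }
  if (!identical(as.integer(meta$format_version), FORMAT_VERSION)) {
    abort(sprintf("unsupported RF container version %s.",
                  meta$format_version),
          class = "twitchtdi_unsupported_version")
  }
  m <- tryCatch(
    as.matrix(utils::read.table(csv_path, sep = ",", header = FALSE)),
    error = function(e) abort("corrupt RF sample matrix.",
                              class = "twitchtdi_io_error"))
  dimnames(m) <- NULL
  if (nrow(m) != meta$n_depth_samples || ncol(m) != meta$n_pulses ||
      anyNA(m)) {
    abort(sprintf(
      "corrupt RF container: expected %d x %d samples, found %d x %d.",
      meta$n_depth_samples, meta$n_pulses, nrow(m), ncol(m)),
      class = "twitchtdi_io_error")
  }
  params <- acquisition_params(
    center_frequency = meta$center_frequency_hz,
    sample_rate = meta$sample_rate_hz,
    prf = meta$prf_hz,
    speed_of_sound = meta$speed_of_sound_mps,
    gate_upper = meta$gate_upper_mm,
    gate_lower = meta$gate_lower_mm,
    n_pulses = meta$n_pulses
  )
  rf_series(m, params, start_time = meta$start_time_s)
}

#' Write and read the per-twitch feature table
#'
#' CSV with one row per twitch: study keys (`subject`, `round`,
#' `twitch_index`, `phase`), torque, segmentation times and the five
#' waveform features.
#'
#' @param features A feature table from [measure_study_features()].
#' @param path CSV path.
#' @return `write_features_csv()` the path invisibly; `read_features_csv()`
#'   a tibble.
#' @export
write_features_csv <- function(features, path) {
  cols <- c("subject", "round", "twitch_index", "phase", "torque_nm",
            "t_onset_s", "t_zero_s", "t_end_s",
            "peak_velocity_mps", "time_to_zero_s", "total_duration_s",
            "peak_vti_m", "peak_strain_rate_per_s")
  keep <- intersect(cols, names(features))
  readr::write_csv(features[, keep], path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
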