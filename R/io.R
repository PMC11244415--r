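#' Read a per-finger accelerometer CSV
#'
#' Reads one finger's recording from a plain CSV export (header row, comma
#' separator, UTF-8). The default schema is `time, ax, ay, az` with time in
#' seconds and acceleration in g; `column_map` remaps differently named
#' columns and `time_unit` / `acceleration_unit` convert from milliseconds
#' or m/s^2. Time is rebased to seconds from recording start.
#'
#' @param path Path to the CSV file.
#' @param finger_label One of [finger_labels()].
#' @param column_map Named character vector mapping canonical names
#'   (`time`, `ax`, `ay`, `az`) to the file's column names.
#' @param sampling_rate Declared sampling rate in Hz. If `NULL`, inferred
#'   from the median timestamp spacing.
#' @param time_unit `"s"` or `"ms"`.
#' @param acceleration_unit `"g"` or `"ms2"` (m/s^2, divided by 9.81).
#' @param sensor_id Sensor identifier to attach.
#' @param full_scale Sensor full scale in g.
#'
#' @return A validated [accel_trace()].
#' @export
read_trace_csv <- function(path, finger_label,
                           column_map = NULL,
                           sampling_rate = NULL,
                           time_unit = c("s", "ms"),
                           acceleration_unit = c("g", "ms2"),
                           sensor_id = basename(path),
                           full_scale = 8) {
  time_unit <- match.arg(time_unit)
  acceleration_unit <- match.arg(acceleration_unit)
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- c(time = "time", ax = "ax", ay = "ay", az = "az")
  if (!is.null(column_map)) wanted[names(column_map)] <- column_map
  missing <- wanted[!wanted %in% names(df)]
  if (length(missing) > 0) {
    abort_format(
      sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
      missing_columns = unname(missing)
    )
  }
  tm <- as.numeric(df[[wanted[["time"]]]])
  if (time_unit == "ms") tm <- tm / 1000
  tm <- tm - tm[1]
  acc <- lapply(wanted[c("ax", "ay", "az")], function(cl) as.numeric(df[[cl]]))
  if (acceleration_unit == "ms2") acc <- lapply(acc, function(v) v / 9.81)
  if (is.null(sampling_rate)) {
    if (length(tm) < 2) abort_data("trace must contain at least 2 samples")
    sampling_rate <- 1 / stats::median(diff(tm))
  }
  accel_trace(
    timestamps = tm, ax = acc[[1]], ay = acc[[2]], az = acc[[3]],
    sampling_rate = sampling_rate, finger_label = finger_label,
    sensor_id = sensor_id, full_scale = full_scale
  )
}

#' Write an acceleration trace to CSV
#'
#' Writes the canonical `time, ax, ay, az` schema at full double precision,
#' so [read_trace_csv()] round-trips to an identical trace.
#'
#' @param trace A valid [accel_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  validate_accel_trace(trace)
  df <- data.frame(
    time = format(trace$timestamps, digits = 17, scientific = FALSE, trim = TRUE),
    ax = format(trace$ax, digits = 17, trim = TRUE),
    ay = format(trace$ay, digits = 17, trim = TRUE),
    az = format(trace$az, digits = 17, trim = TRUE)
  )
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) abort_format(sprintf("cannot write to %s: %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Write a tidy per-trial metrics table
#'
#' One row per (participant, test, finger or finger pair), stable column
#' order taken from the first row. All rows must share the same fields.
#'
#' @param records A data frame / tibble of metric rows, or a list of
#'   homogeneous named lists.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- as.data.frame(records)
  } else {
    if (length(records) == 0) {
      abort_data("cannot infer columns from an empty record list; pass a data frame")
    }
    nms <- names(records[[1]])
    ok <- vapply(records, function(r) identical(names(r), nms), logical(1))
    if (!all(ok)) {
      abort_data(sprintf("heterogeneous rows: row %d has different fields", which(!ok)[1]))
    }
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session configuration from YAML
#'
#' The YAML file mirrors [session_config()]: top-level keys
#' `simultaneity_threshold`, `excursion_window`, `full_scale`,
#' `sampling_rate_expected`, and a `detection` block with
#' `min_prominence`, `min_separation`, `smoothing_halfwidth`, `polarity`.
#' Missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  det_args <- y$detection %||% list()
  det <- do.call(detection_params, det_args)
  args <- y[setdiff(names(y), "detection")]
  do.call(session_config, c(list(detection = det), args))
}

#' Write a session configuration to YAML
#'
#' @param config A [session_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  y <- list(
    simultaneity_threshold = config$simultaneity_threshold,
    excursion_window = config$excursion_window,
    full_scale = config$full_scale,
    sampling_rate_expected = config$sampling_rate_expected,
    detection = list(
      min_prominence = config$detection$min_prominence,
      min_separation = config$detection$min_separation,
      smoothing_halfwidth = config$detection$smoothing_halfwidth,
      polarity = config$detection$polarity
    )
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
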