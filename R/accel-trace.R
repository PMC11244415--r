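#' Finger labels recognised by the tapping-test protocol
#'
#' Uni-manual tests use the index and middle finger of the dominant hand;
#' bi-manual tests use the index fingers of both hands.
#'
#' @export
finger_labels <- function() {
  c("index_dom", "middle_dom", "index_right", "index_left")
}

#' Tapping-test types
#'
#' `UniSIM`/`UniALT` are uni-manual (index + middle finger of the dominant
#' hand, tapping simultaneously / alternating); `BimSIM`/`BimALT` are
#' bi-manual (both index fingers).
#'
#' @export
test_types <- function() {
  c("UniSIM", "UniALT", "BimSIM", "BimALT")
}

#' Construct a tri-axial acceleration trace for one finger
#'
#' An `accel_trace` holds one finger's uniformly sampled tri-axial
#' accelerometer record in units of g. Validation enforces strictly
#' increasing, uniformly spaced timestamps (within 1% relative tolerance of
#' the nominal sampling interval) and that all samples lie within the sensor
#' full scale.
#'
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing, uniformly spaced.
#' @param ax,ay,az Acceleration along the x/y/z axes in g, one value per
#'   timestamp.
#' @param sampling_rate Nominal sampling rate in Hz (default 120, the
#'   recording-mode rate of the wearable IMU the protocol targets).
#' @param finger_label One of [finger_labels()].
#' @param sensor_id Free-text sensor identifier.
#' @param full_scale Sensor full scale in g (default 8); samples outside
#'   `[-full_scale, full_scale]` are rejected.
#'
#' @return An object of class `accel_trace`: a list with fields
#'   `sensor_id`, `finger_label`, `sampling_rate`, `timestamps`, `ax`, `ay`,
#'   `az`, `full_scale`.
#' @export
accel_trace <- function(timestamps, ax, ay, az,
                        sampling_rate = 120,
                        finger_label = "index_dom",
                        sensor_id = "synthetic",
                        full_scale = 8) {
  x <- structure(
    list(
      sensor_id = as.character(sensor_id),
      finger_label = match.arg(finger_label, finger_labels()),
      sampling_rate = as.numeric(sampling_rate),
      timestamps = as.numeric(timestamps),
      ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
      full_scale = as.numeric(full_scale)
    ),
    class = "accel_trace"
  )
  validate_accel_trace(x)
}

#' Validate an acceleration trace
#'
#' @param x An `accel_trace`.
#' @return `x`, invisibly unchanged, if valid; otherwise a typed error.
#' @export
validate_accel_trace <- function(x) {
  if (!inherits(x, "accel_trace")) abort_data("not an accel_trace object")
  n <- length(x$timestamps)
  if (n < 2) abort_data("trace must contain at least 2 samples")
  lens <- c(length(x$ax), length(x$ay), length(x$az))
  if (any(lens != n)) {
    abort_data(sprintf(
      "axis series lengths (%s) do not match %d timestamps",
      paste(lens, collapse = ", "), n
    ))
  }
  if (!is.finite(x$sampling_rate) || x$sampling_rate <= 0) {
    abort_data("sampling_rate must be a positive number")
  }
  dt <- diff(x$timestamps)
  if (any(dt <= 0)) {
    abort_data(
      sprintf("timestamps not strictly increasing at row %d", which(dt <= 0)[1] + 1L),
      row = which(dt <= 0)[1] + 1L
    )
  }
  nominal <- 1 / x$sampling_rate
  if (any(abs(dt - nominal) > 0.01 * nominal)) {
    measured <- 1 / stats::median(dt)
    abort_data(
      sprintf(
        "irregular sampling: declared %.6g Hz, measured %.6g Hz (spacing off by > 1%%)",
        x$sampling_rate, measured
      ),
      measured_rate = measured
    )
  }
  acc <- c(x$ax, x$ay, x$az)
  if (any(!is.finite(acc))) abort_data("non-finite acceleration values")
  if (any(abs(acc) > x$full_scale)) {
    abort_data(sprintf("acceleration exceeds sensor full scale of %g g", x$full_scale))
  }
  invisible(x)
}

#' Duration of a trace in seconds
#'
#' @param trace An `accel_trace`.
#' @return Last timestamp minus first timestamp, in seconds.
#' @export
trace_duration <- function(trace) {
  validate_accel_trace(trace)
  diff(range(trace$timestamps))
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf(
    "<accel_trace> %s (%s): %d samples @ %g Hz, %.2f s, full scale +/- %g g\n",
    x$finger_label, x$sensor_id, length(x$timestamps), x$sampling_rate,
    trace_duration(x), x$full_scale
  ))
  invisible(x)
}

#' Construct a trial record (one test execution)
#'
#' A trial pairs the two finger traces recorded during one tapping test.
#' Uni-manual tests must carry the `index_dom`/`middle_dom` pair, bi-manual
#' tests the `index_right`/`index_left` pair, and the two traces must
#' overlap in time for at least 90% of the trial duration (synchronization
#' between sensors is assumed done upstream; only overlap is validated
#' here).
#'
#' @param participant_id Free-text participant identifier.
#' @param test_type One of [test_types()].
#' @param trace_1,trace_2 `accel_trace` objects for the two fingers.
#' @param duration Trial duration in seconds; defaults to the longer trace.
#' @param metadata Optional named list (e.g. `age`, `index_length`,
#'   `middle_length`).
#'
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(participant_id, test_type, trace_1, trace_2,
                         duration = NULL, metadata = list()) {
  test_type <- match.arg(test_type, test_types())
  validate_accel_trace(trace_1)
  validate_accel_trace(trace_2)
  if (identical(trace_1$finger_label, trace_2$finger_label)) {
    abort_data("the two traces of a trial must come from different fingers")
  }
  expected <- if (startsWith(test_type, "Uni")) {
    c("index_dom", "middle_dom")
  } else {
    c("index_right", "index_left")
  }
  got <- sort(c(trace_1$finger_label, trace_2$finger_label))
  if (!identical(got, sort(expected))) {
    abort_data(sprintf(
      "%s requires finger pair {%s}; got {%s}",
      test_type, paste(expected, collapse = ", "), paste(got, collapse = ", ")
    ))
  }
  if (is.null(duration)) {
    duration <- max(trace_duration(trace_1), trace_duration(trace_2))
  }
  overlap <- min(max(trace_1$timestamps), max(trace_2$timestamps)) -
    max(min(trace_1$timestamps), min(trace_2$timestamps))
  if (overlap < 0.9 * duration) {
    abort_data(sprintf(
      "traces overlap for %.2f s, less than 90%% of the %.2f s trial", overlap, duration
    ))
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      test_type = test_type,
      trace_1 = trace_1, trace_2 = trace_2,
      duration = as.numeric(duration),
      metadata = metadata
    ),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> participant %s, %s, %.1f s (%s vs %s)\n",
    x$participant_id, x$test_type, x$duration,
    x$trace_1$finger_label, x$trace_2$finger_label
  ))
  invisible(x)
}

#' Session configuration
#'
#' Bundles the tunable parameters of a measurement session: tap-detection
#' parameters, the simultaneity threshold (0.1 s by default, the empirical
#' worst-case simultaneity error of the reference test), the excursion
#' window length (5 s), the sensor full scale and expected sampling rate.
#'
#' @param detection A [detection_params()] object.
#' @param simultaneity_threshold Seconds; mean |inter-finger tap delay|
#'   below this classifies a simultaneous test as passed.
#' @param excursion_window Seconds; length of the non-overlapping windows
#'   over which tap amplitude excursions are averaged.
#' @param full_scale Sensor full scale in g.
#' @param sampling_rate_expected Expected sampling rate in Hz.
#'
#' @return An object of class `session_config`.
#' @export
session_config <- function(detection = detection_params(),
                           simultaneity_threshold = 0.1,
                           excursion_window = 5,
                           full_scale = 8,
                           sampling_rate_expected = 120) {
  vals <- c(simultaneity_threshold, excursion_window, full_scale, sampling_rate_expected)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_config("all session parameters must be strictly positive")
  }
  structure(
    list(
      detection = detection,
      simultaneity_threshold = simultaneity_threshold,
      excursion_window = excursion_window,
      full_scale = full_scale,
      sampling_rate_expected = sampling_rate_expected
    ),
    class = "session_config"
  )
}
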