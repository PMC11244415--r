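#' Tap-detection parameters
#'
#' Controls the conversion of a 1-D acceleration signal into tap events.
#' Peaks are local maxima whose topographic prominence reaches
#' `min_prominence`; peaks closer together than `min_separation` are pruned
#' keeping the more prominent one. Defaults are conservative against noise
#' spikes while permissive for fast tapping (0.08 s is below the shortest
#' plausible tap period at maximal speed).
#'
#' @param min_prominence Minimum topographic prominence in g (> 0).
#' @param min_separation Minimum time between retained peaks in seconds
#'   (>= 0).
#' @param smoothing_halfwidth Moving-average half width in samples
#'   (0 = no smoothing; a value `h` averages over `2h + 1` samples).
#' @param polarity `"positive"` detects upward spikes, `"negative"`
#'   downward spikes (the signal is negated first), `"auto"` picks the side
#'   with the larger robust reach from the median. Tap deceleration may
#'   register as negative spikes depending on sensor mounting.
#'
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_prominence = 0.5,
                             min_separation = 0.08,
                             smoothing_halfwidth = 0L,
                             polarity = c("positive", "negative", "auto")) {
  polarity <- match.arg(polarity)
  if (!is.finite(min_prominence) || min_prominence <= 0) {
    abort_config("min_prominence must be > 0")
  }
  if (!is.finite(min_separation) || min_separation < 0) {
    abort_config("min_separation must be >= 0")
  }
  if (!is.finite(smoothing_halfwidth) || smoothing_halfwidth < 0 ||
      smoothing_halfwidth != round(smoothing_halfwidth)) {
    abort_config("smoothing_halfwidth must be a non-negative integer")
  }
  structure(
    list(
      min_prominence = min_prominence,
      min_separation = min_separation,
      smoothing_halfwidth = as.integer(smoothing_halfwidth),
      polarity = polarity
    ),
    class = "detection_params"
  )
}

#' Construct a series of detected tap events
#'
#' @param peak_times Event times in seconds, strictly increasing.
#' @param peak_amplitudes Signal value at each event, in g.
#' @param source_finger One of [finger_labels()].
#' @param detection_params The [detection_params()] snapshot that produced
#'   the series.
#' @return An object of class `tap_series`.
#' @export
tap_series <- function(peak_times, peak_amplitudes,
                       source_finger = "index_dom",
                       detection_params = NULL) {
  peak_times <- as.numeric(peak_times)
  peak_amplitudes <- as.numeric(peak_amplitudes)
  if (length(peak_times) != length(peak_amplitudes)) {
    abort_data("peak_times and peak_amplitudes must have equal length")
  }
  if (length(peak_times) > 1 && any(diff(peak_times) <= 0)) {
    abort_data("peak_times must be strictly increasing")
  }
  if (any(!is.finite(peak_amplitudes))) abort_data("peak amplitudes must be finite")
  structure(
    list(
      source_finger = match.arg(source_finger, finger_labels()),
      peak_times = peak_times,
      peak_amplitudes = peak_amplitudes,
      detection_params = detection_params
    ),
    class = "tap_series"
  )
}

#' @export
print.tap_series <- function(x, ...) {
  cat(sprintf(
    "<tap_series> %s: %d taps%s\n",
    x$source_finger, length(x$peak_times),
    if (length(x$peak_times) > 1) {
      sprintf(", span %.2f s, median inter-time %.3f s",
              diff(range(x$peak_times)), stats::median(diff(x$peak_times)))
    } else ""
  ))
  invisible(x)
}

#' @export
length.tap_series <- function(x) length(x$peak_times)

#' Select the axis with the greatest acceleration excursion
#'
#' Tapping shows up on the axis perpendicular to the tapping surface; that
#' axis is found as the one maximising the robust excursion, defined as the
#' difference between the 99th and 1st percentile of the axis signal
#' (robust against isolated spikes). Exact ties are broken in the fixed
#' order z > y > x, z being the expected axis for the standard fingertip
#' mounting.
#'
#' @param trace An [accel_trace()].
#' @return A list with `axis` (`"x"`, `"y"` or `"z"`), `signal` (the 1-D
#'   series of that axis) and `excursion` (the robust excursion in g).
#' @export
select_motion_axis <- function(trace) {
  validate_accel_trace(trace)
  axes <- list(z = trace$az, y = trace$ay, x = trace$ax)
  exc <- vapply(
    axes,
    function(v) diff(stats::quantile(v, c(0.01, 0.99), names = FALSE)),
    numeric(1)
  )
  if (max(exc) <= 0) {
    # sparse activity (e.g. a single pulse) can hide inside the trimmed
    # quantile range; fall back to the full excursion before giving up
    exc <- vapply(axes, function(v) diff(range(v)), numeric(1))
  }
  if (max(exc) <= 0) {
    abort_degenerate("degenerate signal: all axes are constant")
  }
  axis <- names(exc)[which.max(exc)] # ties: z > y > x by ordering
  list(
    axis = axis,
    signal = trace[[paste0("a", axis)]],
    excursion = unname(exc[axis])
  )
}

# Indices of local maxima; a plateau of equal values bounded below on both
# sides counts once, at its first sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  sn <- s[nz]
  k <- which(sn[-length(sn)] > 0 & sn[-1] < 0)
  nz[k] + 1L
}

# Topographic prominence of peak at index i: height minus the higher of the
# two key saddles, where each side's saddle is the minimum between the peak
# and the nearest strictly higher sample (or the signal edge).
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(i) {
    h <- x[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < left_min) left_min <- x[j]
      j <- j - 1L
    }
    right_min <- h
    j <- i + 1L
    n <- length(x)
    while (j <= n && x[j] <= h) {
      if (x[j] < right_min) right_min <- x[j]
      j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

moving_average <- function(x, halfwidth) {
  if (halfwidth == 0L) return(x)
  n <- length(x)
  w <- 2L * halfwidth + 1L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - halfwidth, 1L)
  hi <- pmin(seq_len(n) + halfwidth, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect tap events in a 1-D acceleration signal
#'
#' After optional polarity handling and moving-average smoothing, local
#' maxima with topographic prominence of at least `min_prominence` are
#' retained; among peaks violating `min_separation` the more prominent one
#' wins (the earlier one on an exact prominence tie). Returned times are
#' the timestamps of the retained samples. When smoothing is enabled, each
#' retained peak is re-localised to the unsmoothed-signal maximum within
#' the smoothing window, so smoothing buys detection robustness without
#' blurring the event time.
#'
#' @param signal Numeric vector of acceleration in g.
#' @param timestamps Sample times in seconds, same length as `signal`.
#' @param params A [detection_params()].
#' @param source_finger Finger label to stamp on the result.
#' @return A [tap_series()].
#' @export
detect_taps <- function(signal, timestamps, params = detection_params(),
                        source_finger = "index_dom") {
  if (!inherits(params, "detection_params")) {
    abort_config("params must be a detection_params object")
  }
  signal <- as.numeric(signal)
  timestamps <- as.numeric(timestamps)
  if (length(signal) != length(timestamps)) {
    abort_data("signal and timestamps must have equal length")
  }
  if (length(signal) < 3) abort_data("signal too short for peak detection (need >= 3 samples)")

  x <- signal
  if (params$polarity == "negative") {
    x <- -x
  } else if (params$polarity == "auto") {
    med <- stats::median(x)
    up <- stats::quantile(x, 0.99, names = FALSE) - med
    down <- med - stats::quantile(x, 0.01, names = FALSE)
    if (down > up) x <- -x
  }
  x_raw <- x
  x <- moving_average(x, params$smoothing_halfwidth)

  peaks <- local_maxima(x)
  if (length(peaks) == 0) {
    return(tap_series(numeric(0), numeric(0), source_finger, params))
  }
  prom <- peak_prominences(x, peaks)
  keep <- prom >= params$min_prominence
  peaks <- peaks[keep]
  prom <- prom[keep]
  if (length(peaks) > 1 && params$min_separation > 0) {
    ord <- order(-prom, timestamps[peaks])
    accepted <- integer(0)
    for (k in ord) {
      t_k <- timestamps[peaks[k]]
      if (length(accepted) == 0 ||
          all(abs(timestamps[peaks[accepted]] - t_k) >= params$min_separation)) {
        accepted <- c(accepted, k)
      }
    }
    peaks <- sort(peaks[accepted])
  }
  if (params$smoothing_halfwidth > 0L && length(peaks) > 0) {
    h <- params$smoothing_halfwidth
    n <- length(x_raw)
    # a 3-sample average keeps the crest sharp while suppressing
    # single-sample noise flips during re-localisation
    x_loc <- moving_average(x_raw, 1L)
    peaks <- vapply(peaks, function(i) {
      lo <- max(1L, i - h)
      win <- x_loc[lo:min(n, i + h)]
      lo + which.max(win) - 1L
    }, integer(1))
    keep <- c(TRUE, diff(peaks) > 0) # drop collisions after re-localisation
    peaks <- peaks[keep]
    return(tap_series(timestamps[peaks], x_raw[peaks], source_finger, params))
  }
  tap_series(timestamps[peaks], x[peaks], source_finger, params)
}

#' Detect taps on the dominant motion axis of a trace
#'
#' Convenience wrapper: [select_motion_axis()] then [detect_taps()].
#'
#' @param trace An [accel_trace()].
#' @param params A [detection_params()].
#' @return A [tap_series()] carrying an extra `axis` attribute.
#' @export
detect_trace_taps <- function(trace, params = detection_params()) {
  sel <- select_motion_axis(trace)
  taps <- detect_taps(sel$signal, trace$timestamps, params, trace$finger_label)
  attr(taps, "axis") <- sel$axis
  taps
}
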