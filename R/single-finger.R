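#' Inter-tap intervals of one finger
#'
#' The inter-tap time is the difference between two consecutive detected
#' tap times; interval `i` is attributed to the time of the later tap, so
#' the series can be regressed against elapsed execution time.
#'
#' @param taps A [tap_series()] with at least 2 events.
#' @return A tibble with columns `event_time` and `inter_time` (seconds),
#'   `n_taps - 1` rows, all `inter_time` > 0.
#' @export
inter_tap_times <- function(taps) {
  stopifnot(inherits(taps, "tap_series"))
  t <- taps$peak_times
  if (length(t) < 2) {
    abort_insufficient(sprintf("need >= 2 taps for inter-tap times, got %d", length(t)))
  }
  tibble::tibble(event_time = t[-1], inter_time = diff(t))
}

#' Fit the fatigue line: inter-tap time versus execution time
#'
#' Ordinary least squares of inter-tap time on elapsed execution time. A
#' positive slope (the line's angular coefficient) means taps slow down
#' over the trial — the fatigue signature; a negative slope indicates
#' speeding up (a training effect). When the inter-times have zero
#' variance the fit is flagged degenerate: the slope is exactly 0 and
#' `r_squared` is reported as 1 by convention (the constant line fits
#' perfectly), keeping downstream aggregation stable.
#'
#' @param event_times Times in seconds (>= 3 values, non-constant).
#' @param inter_times Inter-tap times in seconds, same length.
#' @return A list with `slope` (s/s), `intercept` (s), `r_squared` in
#'   \[0, 1\], and logical `degenerate`.
#' @export
fit_fatigue_line <- function(event_times, inter_times) {
  event_times <- as.numeric(event_times)
  inter_times <- as.numeric(inter_times)
  if (length(event_times) != length(inter_times)) {
    abort_data("event_times and inter_times must have equal length")
  }
  if (length(event_times) < 3) {
    abort_insufficient(sprintf("need >= 3 points for a line fit, got %d", length(event_times)))
  }
  if (stats::var(event_times) == 0) {
    abort_degenerate("event_times have zero variance; the line fit is undefined")
  }
  ss_tot <- sum((inter_times - mean(inter_times))^2)
  if (ss_tot == 0) {
    return(list(slope = 0, intercept = mean(inter_times), r_squared = 1, degenerate = TRUE))
  }
  fit <- stats::lm(inter_times ~ event_times)
  cf <- unname(stats::coef(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  list(
    slope = cf[2],
    intercept = cf[1],
    r_squared = 1 - ss_res / ss_tot,
    degenerate = FALSE
  )
}

#' Windowed acceleration excursion
#'
#' The trial is partitioned into consecutive non-overlapping windows of
#' `window` seconds (the last window may be shorter). Each tap's excursion
#' is its crest value minus the minimum signal value within plus/minus half
#' the local inter-tap interval around the peak — an amplitude swing that
#' is invariant to a constant signal offset. Each window's value is the
#' mean excursion of the taps falling in it; windows without taps are
#' reported as `NA` and omitted from the mean/std (zero-filling them would
#' bias the mean downward).
#'
#' @param signal Numeric acceleration signal in g (the motion axis).
#' @param timestamps Sample times, same length as `signal`.
#' @param taps A [tap_series()] with at least one event.
#' @param window Window length in seconds (default 5).
#' @param raw_crest If `TRUE`, use the crest value itself instead of
#'   crest-minus-local-minimum (not offset-invariant; off by default).
#' @return A list with `window_excursions` (one value per window, `NA` for
#'   empty windows), `excursion_mean`, `excursion_std` (sample std over
#'   non-empty windows; `NA` with fewer than 2), and `per_tap_excursions`.
#' @export
windowed_excursion <- function(signal, timestamps, taps, window = 5,
                               raw_crest = FALSE) {
  stopifnot(inherits(taps, "tap_series"))
  signal <- as.numeric(signal)
  timestamps <- as.numeric(timestamps)
  if (length(signal) != length(timestamps)) {
    abort_data("signal and timestamps must have equal length")
  }
  tt <- taps$peak_times
  if (length(tt) == 0) abort_insufficient("no taps: excursion undefined")
  if (!is.finite(window) || window <= 0) abort_config("window must be > 0")

  t0 <- timestamps[1]
  duration <- timestamps[length(timestamps)] - t0
  n_windows <- max(1L, as.integer(ceiling(duration / window)))

  # local half-interval per tap: half the mean of the adjacent inter-tap
  # gaps (single gap at the ends); with one tap, the whole trace
  half <- if (length(tt) == 1) {
    rep(duration / 2, 1)
  } else {
    gaps <- diff(tt)
    prev_gap <- c(gaps[1], gaps)
    next_gap <- c(gaps, gaps[length(gaps)])
    (prev_gap + next_gap) / 4
  }

  per_tap <- vapply(seq_along(tt), function(i) {
    idx_peak <- which.min(abs(timestamps - tt[i]))
    crest <- signal[idx_peak]
    if (raw_crest) return(crest)
    in_win <- timestamps >= tt[i] - half[i] & timestamps <= tt[i] + half[i]
    crest - min(signal[in_win])
  }, numeric(1))

  win_idx <- pmin(as.integer(floor((tt - t0) / window)) + 1L, n_windows)
  window_excursions <- vapply(seq_len(n_windows), function(w) {
    v <- per_tap[win_idx == w]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))

  filled <- window_excursions[!is.na(window_excursions)]
  list(
    window_excursions = window_excursions,
    excursion_mean = mean(filled),
    excursion_std = if (length(filled) >= 2) stats::sd(filled) else NA_real_,
    per_tap_excursions = per_tap
  )
}

#' Percent difference of excursion means relative to a reference test
#'
#' `100 * (reference - other) / reference`; positive values quantify
#' amplitude loss relative to the reference condition.
#'
#' @param reference_mean Reference excursion mean in g (> 0).
#' @param other_mean Comparison excursion mean in g.
#' @return Percent difference.
#' @export
excursion_percent_difference <- function(reference_mean, other_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0) {
    abort_domain("reference excursion mean must be > 0")
  }
  100 * (reference_mean - other_mean) / reference_mean
}

#' All single-finger metrics for one trace
#'
#' Runs axis selection, tap detection, inter-tap intervals, the fatigue
#' line fit and the windowed excursion in one call.
#'
#' @param trace An [accel_trace()].
#' @param params A [detection_params()].
#' @param window Excursion window length in seconds.
#' @return An object of class `single_finger_metrics`: a list with
#'   `finger`, `n_taps`, `inter_times` (tibble), `slope`, `intercept`,
#'   `r_squared`, `degenerate`, `window_excursions`, `excursion_mean`,
#'   `excursion_std`.
#' @export
single_finger_metrics <- function(trace, params = detection_params(), window = 5) {
  sel <- select_motion_axis(trace)
  taps <- detect_taps(sel$signal, trace$timestamps, params, trace$finger_label)
  it <- inter_tap_times(taps)
  fit <- fit_fatigue_line(it$event_time, it$inter_time)
  exc <- windowed_excursion(sel$signal, trace$timestamps, taps, window)
  structure(
    list(
      finger = trace$finger_label,
      axis = sel$axis,
      n_taps = length(taps$peak_times),
      taps = taps,
      inter_times = it,
      slope = fit$slope,
      intercept = fit$intercept,
      r_squared = fit$r_squared,
      degenerate = fit$degenerate,
      window_excursions = exc$window_excursions,
      excursion_mean = exc$excursion_mean,
      excursion_std = exc$excursion_std
    ),
    class = "single_finger_metrics"
  )
}

#' @export
print.single_finger_metrics <- function(x, ...) {
  cat(sprintf(
    "<single_finger_metrics> %s (axis %s): %d taps, slope %.4f s/s (R2 %.3f), excursion %.3f g\n",
    x$finger, x$axis, x$n_taps, x$slope, x$r_squared, x$excursion_mean
  ))
  invisible(x)
}
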