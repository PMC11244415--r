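#' Parameters of the synthetic tapping-trial generator
#'
#' The generator emulates the acquisition chain of an instrumented
#' tapping test: quasi-periodic biphasic tap pulses with timing drift
#' (the fatigue-slope ground truth), Gaussian timing jitter, an
#' inter-finger offset (near zero for simultaneous tests, near half the
#' tap period for alternate tests), stepwise amplitude decay, and white
#' sensor noise. Every draw is reproducible from `seed`.
#'
#' @param duration Trial length in seconds (default 30, the protocol's
#'   test duration).
#' @param sampling_rate Hz (default 120, the sensor's recording rate).
#' @param base_interval Base inter-tap period T0 in seconds (default
#'   0.25 s, i.e. 4 taps/s — a comfortable "as fast as possible" rate for
#'   a healthy adult).
#' @param drift Fatigue slope m in s/s: the inter-tap interval grows by
#'   `m * t` at elapsed time t (positive = slowing).
#' @param timing_jitter Standard deviation of per-interval Gaussian jitter
#'   in seconds.
#' @param pulse_amplitude Crest acceleration A of a tap pulse in g
#'   (default 2 g, a typical fingertip tap deceleration).
#' @param amplitude_decay Fractional amplitude loss per 5 s window
#'   (0 = none; 0.1 = each window's pulses are 10% weaker than the last).
#' @param pulse_width Total pulse support in seconds (< `base_interval`).
#' @param inter_finger_mode `"simultaneous"` (per-event offset
#'   `offset + N(0, offset_jitter)`) or `"alternate"` (per-event offset
#'   `base_interval / 2 + N(0, offset_jitter)`).
#' @param offset Simultaneous-mode inter-finger offset delta0 in seconds.
#' @param offset_jitter Standard deviation of the per-event offset in
#'   seconds.
#' @param noise White sensor-noise standard deviation in g.
#' @param seed Integer seed; all realisations are deterministic in it.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(duration = 30, sampling_rate = 120,
                         base_interval = 0.25, drift = 0,
                         timing_jitter = 0, pulse_amplitude = 2,
                         amplitude_decay = 0, pulse_width = 0.1,
                         inter_finger_mode = c("simultaneous", "alternate"),
                         offset = 0, offset_jitter = 0,
                         noise = 0.05, seed = 1L) {
  inter_finger_mode <- match.arg(inter_finger_mode)
  if (duration <= 0 || sampling_rate <= 0) abort_config("duration and sampling_rate must be > 0")
  if (base_interval <= 0) abort_config("base_interval must be > 0")
  if (timing_jitter < 0 || offset_jitter < 0 || noise < 0) {
    abort_config("jitter and noise standard deviations must be >= 0")
  }
  if (pulse_amplitude <= 0) abort_config("pulse_amplitude must be > 0")
  if (pulse_width <= 0 || pulse_width >= base_interval) {
    abort_config("pulse_width must satisfy 0 < pulse_width < base_interval")
  }
  if (amplitude_decay < 0 || amplitude_decay >= 1) {
    abort_config("amplitude_decay must be in [0, 1)")
  }
  structure(
    list(
      duration = duration, sampling_rate = sampling_rate,
      base_interval = base_interval, drift = drift,
      timing_jitter = timing_jitter, pulse_amplitude = pulse_amplitude,
      amplitude_decay = amplitude_decay, pulse_width = pulse_width,
      inter_finger_mode = inter_finger_mode,
      offset = offset, offset_jitter = offset_jitter,
      noise = noise, seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

# One global seed fans out into per-finger / per-purpose substreams so each
# trace is independently reproducible. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 2147483647) * 48271 + stream * 7919) %% 2147483647 + 1
}

#' Ground-truth tap times for one finger
#'
#' Finger 1 follows the recurrence
#' `t[i+1] = t[i] + max(2 * pulse_width, T0 + m * t[i] + jitter[i])`
#' starting at `t[1] = T0`, stopping before the pulse would leave the
#' trial; finger 2 adds the per-event inter-finger offset of the chosen
#' mode to finger 1's times.
#'
#' @param params A [synth_params()].
#' @param finger_index 1 or 2.
#' @return Numeric vector of tap times in `[0, duration)`.
#' @export
generate_tap_times <- function(params, finger_index = 1) {
  stopifnot(inherits(params, "synth_params"))
  if (!finger_index %in% c(1, 2)) abort_config("finger_index must be 1 or 2")
  p <- params
  margin <- p$pulse_width # room for the pulse tail at the trial end
  t1 <- local({
    set.seed(derive_seed(p$seed, 1))
    out <- numeric(0)
    t <- p$base_interval
    while (t < p$duration - margin) {
      out <- c(out, t)
      step <- p$base_interval + p$drift * t +
        if (p$timing_jitter > 0) stats::rnorm(1, 0, p$timing_jitter) else 0
      t <- t + max(2 * p$pulse_width, step)
    }
    out
  })
  if (finger_index == 1) return(t1)
  set.seed(derive_seed(p$seed, 2))
  base_off <- if (p$inter_finger_mode == "alternate") p$base_interval / 2 else p$offset
  offs <- base_off +
    if (p$offset_jitter > 0) stats::rnorm(length(t1), 0, p$offset_jitter) else 0
  t2 <- t1 + offs
  kept <- which(t2 >= p$pulse_width / 4 & t2 < p$duration - margin)
  structure(t2[kept], kept = kept)
}

#' Render tap times into a tri-axial acceleration trace
#'
#' The motion axis (z) carries one biphasic raised-cosine pulse per tap —
#' a positive crest of the current pulse amplitude followed by a trough of
#' half that depth, over `pulse_width` seconds — plus white Gaussian
#' noise; x and y carry noise only. The crest of each rendered pulse
#' coincides with its tap time to within half a sample. The pulse shape
#' is a modelling choice (any sharp unimodal crest suits prominence-based
#' detection), not a claim about real tap waveforms.
#'
#' @param tap_times Tap times in seconds, inside the trial.
#' @param params A [synth_params()].
#' @param finger_label Label for the produced trace.
#' @param finger_index 1 or 2 (selects the noise substream).
#' @return An [accel_trace()].
#' @export
render_trace <- function(tap_times, params, finger_label = "index_dom",
                         finger_index = 1) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  if (length(tap_times) > 0 &&
      (min(tap_times) < 0 || max(tap_times) >= p$duration)) {
    abort_data("tap times must lie within [0, duration)")
  }
  n <- round(p$duration * p$sampling_rate)
  tm <- (seq_len(n) - 1) / p$sampling_rate
  z <- numeric(n)
  pw <- p$pulse_width
  for (tau in tap_times) {
    amp <- p$pulse_amplitude * (1 - p$amplitude_decay)^floor(tau / 5)
    i0 <- max(1L, ceiling((tau - pw / 4) * p$sampling_rate) + 1L)
    i1 <- min(n, floor((tau + 3 * pw / 4) * p$sampling_rate) + 1L)
    s <- tm[i0:i1] - tau
    lobe <- ifelse(
      abs(s) <= pw / 4,
      amp / 2 * (1 + cos(4 * pi * s / pw)),
      ifelse(
        s > pw / 4 & s <= 3 * pw / 4,
        -amp / 4 * (1 + cos(4 * pi * (s - pw / 2) / pw)),
        0
      )
    )
    z[i0:i1] <- z[i0:i1] + lobe
  }
  set.seed(derive_seed(p$seed, 10 + finger_index))
  full_scale <- 8
  clamp <- function(v) pmax(pmin(v, full_scale), -full_scale)
  noise <- function() if (p$noise > 0) stats::rnorm(n, 0, p$noise) else numeric(n)
  accel_trace(
    timestamps = tm,
    ax = clamp(noise()), ay = clamp(noise()), az = clamp(z + noise()),
    sampling_rate = p$sampling_rate,
    finger_label = finger_label,
    sensor_id = sprintf("synthetic-%d", finger_index),
    full_scale = full_scale
  )
}

#' Generate a complete ground-truthed trial
#'
#' Builds the two-finger [trial_record()] for a test type together with
#' its generation ground truth. Uni-manual tests use the
#' `index_dom`/`middle_dom` pair, bi-manual tests `index_right`/
#' `index_left`; simultaneous tests use the simultaneous offset mode and
#' alternate tests the half-period offset mode regardless of the mode in
#' `params`.
#'
#' @param test_type One of [test_types()].
#' @param params A [synth_params()].
#' @param participant_id Identifier stamped on the trial.
#' @return A list with `trial` (a [trial_record()]) and `truth` (tap
#'   times per finger, the true drift, the per-event offsets, and the
#'   parameter snapshot).
#' @export
generate_trial <- function(test_type, params = synth_params(),
                           participant_id = "synthetic") {
  test_type <- match.arg(test_type, test_types())
  mode <- if (endsWith(test_type, "ALT")) "alternate" else "simultaneous"
  p <- params
  p$inter_finger_mode <- mode
  labels <- if (startsWith(test_type, "Uni")) {
    c("index_dom", "middle_dom")
  } else {
    c("index_right", "index_left")
  }
  t1 <- generate_tap_times(p, 1)
  t2 <- generate_tap_times(p, 2)
  trial <- trial_record(
    participant_id = participant_id,
    test_type = test_type,
    trace_1 = render_trace(t1, p, labels[1], 1),
    trace_2 = render_trace(t2, p, labels[2], 2),
    duration = p$duration
  )
  list(
    trial = trial,
    truth = list(
      tap_times_1 = t1, tap_times_2 = as.numeric(t2),
      slope = p$drift,
      offsets = as.numeric(t2) - t1[attr(t2, "kept")],
      params = p
    )
  )
}

#' Detection parameters matched to the generator's pulse amplitude
#'
#' For noisy traces, reliable separation of tap pulses from baseline noise
#' bumps needs a prominence threshold tied to the pulse scale and light
#' smoothing: with a biphasic pulse the deep trough inflates the
#' topographic prominence of nearby noise maxima, so the threshold is set
#' to half the pulse amplitude and a 5-sample moving average is applied.
#'
#' @param params A [synth_params()].
#' @return A [detection_params()].
#' @export
synth_detection_params <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  detection_params(
    min_prominence = params$pulse_amplitude / 2,
    min_separation = min(0.08, params$base_interval / 3),
    smoothing_halfwidth = 2L
  )
}
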