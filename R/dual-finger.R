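#' Pair tap events from two fingers
#'
#' Two pairing rules are provided because the right rule depends on how
#' well the two detections line up. `index_aligned` (default) truncates
#' both series to the shorter length and pairs the i-th tap of one finger
#' with the i-th of the other — the natural rule when both fingers produced
#' the same number of taps. `nearest` pairs each peak of the shorter series
#' with a peak of the longer one so that the total |delta t| over all
#' pairs is minimal (an order-preserving assignment solved exactly by
#' dynamic programming), which is robust to missed detections at the cost
#' of possibly skipping events on the longer side.
#'
#' @param taps1,taps2 [tap_series()] objects, both non-empty.
#' @param mode `"index_aligned"` or `"nearest"`.
#' @return A tibble with columns `t1`, `t2` (seconds), sorted by `t1`.
#' @export
pair_taps <- function(taps1, taps2, mode = c("index_aligned", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(taps1, "tap_series"), inherits(taps2, "tap_series"))
  t1 <- taps1$peak_times
  t2 <- taps2$peak_times
  if (length(t1) == 0 || length(t2) == 0) {
    abort_insufficient("both tap series must be non-empty for pairing")
  }
  if (mode == "index_aligned") {
    n <- min(length(t1), length(t2))
    out <- tibble::tibble(t1 = t1[seq_len(n)], t2 = t2[seq_len(n)])
  } else {
    swap <- length(t1) > length(t2)
    a <- if (swap) t2 else t1 # shorter: every element matched
    b <- if (swap) t1 else t2
    m <- length(a)
    n <- length(b)
    # dp[i+1, j+1]: min total |dt| matching a[1..i] into b[1..j], in order
    dp <- matrix(Inf, m + 1, n + 1)
    dp[1, ] <- 0
    for (i in seq_len(m)) {
      for (j in i:(n - m + i)) {
        dp[i + 1, j + 1] <- min(
          dp[i + 1, j], # skip b[j]
          dp[i, j] + abs(a[i] - b[j]) # pair a[i] with b[j]
        )
      }
    }
    # backtrack the pairing
    pa <- integer(m)
    j <- n
    for (i in m:1) {
      while (j > i && dp[i + 1, j + 1] == dp[i + 1, j]) j <- j - 1
      pa[i] <- j
      j <- j - 1
    }
    out <- if (swap) {
      tibble::tibble(t1 = b[pa], t2 = a)
    } else {
      tibble::tibble(t1 = a, t2 = b[pa])
    }
  }
  out[order(out$t1), ]
}

#' Simultaneity/alternation timing metrics for paired taps
#'
#' For each pair the absolute inter-finger time difference is computed;
#' the per-trial summary is its mean and sample standard deviation. For
#' simultaneous tests these differences estimate the time mismatch between
#' taps meant to be aligned (ideally 0); for alternate tests they estimate
#' the alternation rhythm (ideally half the tap period).
#'
#' @param pairs A tibble from [pair_taps()] (columns `t1`, `t2`).
#' @return A list with `sa_times` (seconds, one per pair), `sa_mean`,
#'   `sa_std` (`NA` with a single pair, never reported as 0), `n_pairs`.
#' @export
sa_time_metrics <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("t1", "t2") %in% names(pairs))) {
    abort_data("pairs must be a data frame with columns t1 and t2")
  }
  n <- nrow(pairs)
  if (n == 0) abort_insufficient("no pairs: timing metrics undefined")
  sa <- abs(pairs$t2 - pairs$t1)
  list(
    sa_times = sa,
    sa_mean = mean(sa),
    sa_std = if (n >= 2) stats::sd(sa) else NA_real_,
    n_pairs = n
  )
}

#' Classify a simultaneous test
#'
#' A simultaneous trial passes when the mean absolute inter-finger tap
#' delay stays strictly under the threshold (default 0.1 s, the empirical
#' worst-case simultaneity error of the easiest reference test). The
#' boundary value itself fails; callers can re-threshold from the raw mean.
#'
#' @param sa_mean Mean absolute inter-finger delay in seconds (>= 0).
#' @param threshold Threshold in seconds (default 0.1).
#' @return `"simultaneous_pass"` or `"simultaneous_fail"`.
#' @export
classify_simultaneity <- function(sa_mean, threshold = 0.1) {
  if (!is.finite(sa_mean) || sa_mean < 0) abort_domain("sa_mean must be >= 0")
  if (!is.finite(threshold) || threshold <= 0) abort_config("threshold must be > 0")
  if (sa_mean < threshold) "simultaneous_pass" else "simultaneous_fail"
}

#' Classify an alternating test
#'
#' Alternation is executed correctly when the inter-finger tap delay is
#' clearly *larger* than what simultaneous tapping produces (a participant
#' who alternates poorly drifts toward simultaneity). Two criteria:
#' `fixed` passes when `sa_mean` exceeds the fixed threshold (default
#' 0.1 s); `adaptive` passes when `sa_mean` exceeds the upper limit
#' `sim_mean + sim_std` of the same participant's simultaneous test of the
#' same manual condition.
#'
#' @param sa_mean Mean absolute inter-finger delay in seconds (>= 0).
#' @param criterion `"fixed"` or `"adaptive"`.
#' @param threshold Fixed-mode threshold in seconds.
#' @param sim_mean,sim_std Reference simultaneous-test metrics (adaptive
#'   mode only).
#' @return `"alternate_pass"` or `"alternate_fail"`.
#' @export
classify_alternation <- function(sa_mean, criterion = c("fixed", "adaptive"),
                                 threshold = 0.1,
                                 sim_mean = NULL, sim_std = NULL) {
  criterion <- match.arg(criterion)
  if (!is.finite(sa_mean) || sa_mean < 0) abort_domain("sa_mean must be >= 0")
  limit <- if (criterion == "fixed") {
    threshold
  } else {
    if (is.null(sim_mean) || is.null(sim_std)) {
      abort_config("adaptive criterion needs sim_mean and sim_std of the matching simultaneous test")
    }
    sim_mean + sim_std
  }
  if (sa_mean > limit) "alternate_pass" else "alternate_fail"
}

#' Cohort task-failure rate
#'
#' @param classifications Character vector of per-participant
#'   classifications (`*_pass` / `*_fail`).
#' @return Percent of failures, unrounded.
#' @export
cohort_task_failure_rate <- function(classifications) {
  if (length(classifications) == 0) abort_domain("empty classification list")
  100 * mean(grepl("_fail$", classifications))
}

#' All dual-finger metrics for one trial
#'
#' Detects taps on both traces, pairs them, computes the inter-finger
#' timing metrics and classifies the trial according to its test type
#' (simultaneous tests against the simultaneity threshold; alternate tests
#' with the fixed or adaptive criterion).
#'
#' @param trial A [trial_record()].
#' @param config A [session_config()].
#' @param pairing Pairing mode passed to [pair_taps()].
#' @param alt_criterion `"fixed"` or `"adaptive"` for alternate tests.
#' @param sim_reference Optional list with `sa_mean`, `sa_std` of the
#'   participant's matching simultaneous test (adaptive criterion).
#' @return An object of class `dual_finger_metrics`: `sa_times`,
#'   `sa_mean`, `sa_std`, `n_pairs`, `classification`, `threshold_used`.
#' @export
dual_finger_metrics <- function(trial, config = session_config(),
                                pairing = c("index_aligned", "nearest"),
                                alt_criterion = c("fixed", "adaptive"),
                                sim_reference = NULL) {
  pairing <- match.arg(pairing)
  alt_criterion <- match.arg(alt_criterion)
  stopifnot(inherits(trial, "trial_record"))
  taps1 <- detect_trace_taps(trial$trace_1, config$detection)
  taps2 <- detect_trace_taps(trial$trace_2, config$detection)
  pairs <- pair_taps(taps1, taps2, pairing)
  m <- sa_time_metrics(pairs)
  simultaneous <- endsWith(trial$test_type, "SIM")
  if (simultaneous) {
    cls <- classify_simultaneity(m$sa_mean, config$simultaneity_threshold)
    thr <- config$simultaneity_threshold
  } else if (alt_criterion == "fixed") {
    cls <- classify_alternation(m$sa_mean, "fixed", config$simultaneity_threshold)
    thr <- config$simultaneity_threshold
  } else {
    cls <- classify_alternation(
      m$sa_mean, "adaptive",
      sim_mean = sim_reference$sa_mean, sim_std = sim_reference$sa_std
    )
    thr <- sim_reference$sa_mean + sim_reference$sa_std
  }
  structure(
    c(m, list(
      classification = cls,
      threshold_used = thr,
      test_type = trial$test_type,
      participant_id = trial$participant_id
    )),
    class = "dual_finger_metrics"
  )
}

#' @export
print.dual_finger_metrics <- function(x, ...) {
  cat(sprintf(
    "<dual_finger_metrics> %s %s: %d pairs, |dt| mean %.4f s (sd %.4f), %s\n",
    x$participant_id, x$test_type, x$n_pairs, x$sa_mean,
    ifelse(is.na(x$sa_std), NA, x$sa_std), x$classification
  ))
  invisible(x)
}
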