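#' Analyse one trial end to end
#'
#' Runs single-finger metrics on both traces and the dual-finger
#' coordination metrics, returning tidy rows ready for
#' [summarize_cohort()] and [write_metrics_table()].
#'
#' @param trial A [trial_record()].
#' @param config A [session_config()].
#' @param pairing,alt_criterion,sim_reference Passed to
#'   [dual_finger_metrics()].
#' @return A list with `single` (tibble, one row per finger) and `dual`
#'   (tibble, one row).
#' @export
analyze_trial <- function(trial, config = session_config(),
                          pairing = "index_aligned",
                          alt_criterion = "fixed",
                          sim_reference = NULL) {
  stopifnot(inherits(trial, "trial_record"))
  singles <- lapply(list(trial$trace_1, trial$trace_2), function(tr) {
    m <- single_finger_metrics(tr, config$detection, config$excursion_window)
    tibble::tibble(
      participant_id = trial$participant_id,
      test_type = trial$test_type,
      finger = m$finger,
      axis = m$axis,
      n_taps = m$n_taps,
      inter_time_mean = mean(m$inter_times$inter_time),
      slope = m$slope,
      intercept = m$intercept,
      r_squared = m$r_squared,
      excursion_mean = m$excursion_mean,
      excursion_std = m$excursion_std
    )
  })
  d <- dual_finger_metrics(trial, config, pairing, alt_criterion, sim_reference)
  list(
    single = do.call(rbind, singles),
    dual = tibble::tibble(
      participant_id = trial$participant_id,
      test_type = trial$test_type,
      n_pairs = d$n_pairs,
      sa_mean = d$sa_mean,
      sa_std = d$sa_std,
      classification = d$classification,
      threshold_used = d$threshold_used
    )
  )
}

#' Analyse a list of trials into a cohort summary
#'
#' @param trials List of [trial_record()] objects.
#' @param config A [session_config()].
#' @param ... Passed to [analyze_trial()].
#' @return A list with `single` and `dual` tibbles (all trials) and
#'   `summary` (a `cohort_summary`).
#' @export
analyze_cohort <- function(trials, config = session_config(), ...) {
  res <- lapply(trials, analyze_trial, config = config, ...)
  single <- do.call(rbind, lapply(res, `[[`, "single"))
  dual <- do.call(rbind, lapply(res, `[[`, "dual"))
  ref_test <- if (!is.null(single) && "UniSIM" %in% single$test_type) "UniSIM" else NULL
  summary <- if (is.null(single)) {
    summarize_cohort(
      tibble::tibble(
        participant_id = character(), test_type = character(),
        finger = character(), slope = numeric(), excursion_mean = numeric()
      ),
      tibble::tibble(
        participant_id = character(), test_type = character(),
        sa_mean = numeric(), sa_std = numeric(), classification = character()
      )
    )
  } else {
    summarize_cohort(single, dual, reference_test = ref_test %||% "UniSIM")
  }
  list(single = single, dual = dual, summary = summary)
}
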