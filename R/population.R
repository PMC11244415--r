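#' Coefficient of variation of repeated tap counts
#'
#' Repeatability statistic for a sensor placement: the sample standard
#' deviation of the tap counts obtained over repeated executions, divided
#' by their mean, times 100. Lower is better; it is invariant to scaling
#' all counts by the same positive factor.
#'
#' @param n_taps_per_repeat Numeric vector of tap counts, one per repeat
#'   (>= 2 values, positive mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(n_taps_per_repeat) {
  x <- as.numeric(n_taps_per_repeat)
  if (length(x) < 2) {
    abort_insufficient(sprintf("need >= 2 repeats for a CV, got %d", length(x)))
  }
  m <- mean(x)
  if (m == 0) abort_domain("zero mean tap count: CV undefined")
  100 * stats::sd(x) / m
}

#' Mean of per-participant CVs
#'
#' @param cv_per_participant Numeric vector of CVs in percent, non-empty.
#' @return Arithmetic mean, in percent.
#' @export
mean_cv <- function(cv_per_participant) {
  x <- as.numeric(cv_per_participant)
  if (length(x) == 0) abort_domain("empty CV list")
  mean(x)
}

#' Fit a Gaussian to a cohort's fatigue slopes
#'
#' The per-participant fatigue slopes of one (test, finger) cell are
#' summarised by their sample mean and sample (n-1) standard deviation,
#' defining the Gaussian used by [sample_fatigue_percentage()].
#'
#' @param slopes Numeric vector of fatigue slopes in s/s (>= 2 values).
#' @param test_type,finger_label Optional provenance labels.
#' @return An object of class `slope_distribution`: `mu`, `sigma`, `n`,
#'   `test_type`, `finger_label`, logical `degenerate` (`sigma == 0`).
#' @export
fit_slope_distribution <- function(slopes, test_type = NA_character_,
                                   finger_label = NA_character_) {
  x <- as.numeric(slopes)
  if (length(x) < 2) {
    abort_insufficient(sprintf("need >= 2 slopes to fit a distribution, got %d", length(x)))
  }
  sigma <- stats::sd(x)
  structure(
    list(
      mu = mean(x), sigma = sigma, n = length(x),
      test_type = test_type, finger_label = finger_label,
      degenerate = sigma == 0
    ),
    class = "slope_distribution"
  )
}

#' Construct a slope distribution from known parameters
#'
#' For applying [sample_fatigue_percentage()] to published cohort
#' summaries rather than raw slopes.
#'
#' @param mu Mean slope in s/s.
#' @param sigma Standard deviation of slopes in s/s (>= 0).
#' @param n Number of participants (>= 2).
#' @inheritParams fit_slope_distribution
#' @return A `slope_distribution`.
#' @export
slope_distribution <- function(mu, sigma, n = 2L, test_type = NA_character_,
                               finger_label = NA_character_) {
  if (!is.finite(sigma) || sigma < 0) abort_domain("sigma must be >= 0")
  structure(
    list(
      mu = mu, sigma = sigma, n = as.integer(n),
      test_type = test_type, finger_label = finger_label,
      degenerate = sigma == 0
    ),
    class = "slope_distribution"
  )
}

#' @export
print.slope_distribution <- function(x, ...) {
  cat(sprintf(
    "<slope_distribution> %s/%s: mu %.4g, sigma %.4g s/s (n = %d)\n",
    x$test_type, x$finger_label, x$mu, x$sigma, x$n
  ))
  invisible(x)
}

#' Sample Fatigue Percentage
#'
#' The probability that the Gaussian fitted to a cohort's fatigue slopes
#' exceeds zero — the complementary CDF of N(mu, sigma) evaluated at 0 —
#' interpreted as the estimated fraction of participants whose tapping
#' slows down over the trial. Values above 0.5 indicate a test whose
#' typical effect is fatigue; below 0.5, a training effect.
#'
#' By default the SFP comes from the fitted Gaussian. `empirical = TRUE`
#' instead returns the observed exceedance fraction of a raw slope vector.
#'
#' @param dist A `slope_distribution` (from [fit_slope_distribution()] or
#'   [slope_distribution()]).
#' @param empirical If `TRUE`, `slopes` must be given and the empirical
#'   fraction of positive slopes is returned.
#' @param slopes Raw slopes for the empirical variant.
#' @return A fraction in \[0, 1\].
#' @export
sample_fatigue_percentage <- function(dist, empirical = FALSE, slopes = NULL) {
  if (empirical) {
    if (is.null(slopes)) abort_config("empirical SFP needs the raw slope vector")
    return(mean(as.numeric(slopes) > 0))
  }
  stopifnot(inherits(dist, "slope_distribution"))
  if (dist$sigma == 0) {
    if (dist$mu > 0) return(1)
    if (dist$mu < 0) return(0)
    abort_degenerate("sigma = 0 with mu = 0: exceedance of a point mass at the boundary is undefined")
  }
  1 - stats::pnorm(0, mean = dist$mu, sd = dist$sigma)
}

#' Summarise a cohort of per-trial metrics
#'
#' Aggregates per-trial single- and dual-finger metrics into the
#' cohort-level summary: per (test, finger) slope distributions and SFP,
#' per-test inter-finger timing aggregates and failure rates, and
#' excursion percent differences of each test against a reference test.
#' Cells with fewer than 2 participants are marked absent (`NA`), never
#' zero-filled.
#'
#' @param single_rows Tibble with columns `participant_id`, `test_type`,
#'   `finger`, `slope`, `excursion_mean` (one row per trial x finger), as
#'   produced by [analyze_trial()].
#' @param dual_rows Tibble with columns `participant_id`, `test_type`,
#'   `sa_mean`, `sa_std`, `classification` (one row per trial).
#' @param reference_test Test whose excursion is the baseline for percent
#'   differences (default `"UniSIM"`).
#' @param reference_finger Finger used for the excursion comparison
#'   (default the dominant/right index, whichever each test has).
#' @return An object of class `cohort_summary` with tibbles
#'   `slope_distributions` (incl. `sfp`), `sa_aggregates`,
#'   `failure_rates`, `excursion_differences`.
#' @export
summarize_cohort <- function(single_rows, dual_rows,
                             reference_test = "UniSIM",
                             reference_finger = c("index_dom", "index_right")) {
  single_rows <- tibble::as_tibble(single_rows)
  dual_rows <- tibble::as_tibble(dual_rows)

  if (nrow(single_rows) == 0) {
    slope_tbl <- tibble::tibble(
      test_type = character(), finger = character(), n = integer(),
      mu = numeric(), sigma = numeric(), sfp = numeric()
    )
    exc_tbl <- tibble::tibble(test_type = character(), percent_difference = numeric())
  } else {
    cells <- unique(single_rows[c("test_type", "finger")])
    slope_tbl <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sub <- single_rows[single_rows$test_type == cells$test_type[i] &
                           single_rows$finger == cells$finger[i], ]
      n <- nrow(sub)
      if (n < 2) {
        return(tibble::tibble(
          test_type = cells$test_type[i], finger = cells$finger[i],
          n = n, mu = NA_real_, sigma = NA_real_, sfp = NA_real_
        ))
      }
      d <- fit_slope_distribution(sub$slope, cells$test_type[i], cells$finger[i])
      sfp <- if (d$degenerate && d$mu == 0) NA_real_ else sample_fatigue_percentage(d)
      tibble::tibble(
        test_type = cells$test_type[i], finger = cells$finger[i],
        n = n, mu = d$mu, sigma = d$sigma, sfp = sfp
      )
    }))

    idx <- single_rows[single_rows$finger %in% reference_finger, ]
    ref <- idx[idx$test_type == reference_test, ]
    exc_tbl <- if (nrow(ref) < 2) {
      tibble::tibble(test_type = character(), percent_difference = numeric())
    } else {
      ref_mean <- mean(ref$excursion_mean)
      others <- setdiff(unique(idx$test_type), reference_test)
      do.call(rbind, lapply(others, function(tt) {
        sub <- idx[idx$test_type == tt, ]
        tibble::tibble(
          test_type = tt,
          percent_difference = if (nrow(sub) < 2) NA_real_ else {
            excursion_percent_difference(ref_mean, mean(sub$excursion_mean))
          }
        )
      })) %||% tibble::tibble(test_type = character(), percent_difference = numeric())
    }
  }

  if (nrow(dual_rows) == 0) {
    sa_tbl <- tibble::tibble(
      test_type = character(), n = integer(),
      sa_mean = numeric(), sa_std = numeric()
    )
    fail_tbl <- tibble::tibble(test_type = character(), failure_rate = numeric())
  } else {
    tts <- unique(dual_rows$test_type)
    sa_tbl <- do.call(rbind, lapply(tts, function(tt) {
      sub <- dual_rows[dual_rows$test_type == tt, ]
      tibble::tibble(
        test_type = tt, n = nrow(sub),
        sa_mean = if (nrow(sub) >= 2) mean(sub$sa_mean) else NA_real_,
        sa_std = if (nrow(sub) >= 2) stats::sd(sub$sa_mean) else NA_real_
      )
    }))
    fail_tbl <- do.call(rbind, lapply(tts, function(tt) {
      sub <- dual_rows[dual_rows$test_type == tt, ]
      tibble::tibble(
        test_type = tt,
        failure_rate = cohort_task_failure_rate(sub$classification)
      )
    }))
  }

  structure(
    list(
      slope_distributions = slope_tbl,
      sa_aggregates = sa_tbl,
      failure_rates = fail_tbl,
      excursion_differences = exc_tbl
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat("Slope distributions / SFP:\n")
  print(x$slope_distributions)
  cat("Inter-finger timing aggregates:\n")
  print(x$sa_aggregates)
  cat("Failure rates:\n")
  print(x$failure_rates)
  cat("Excursion percent differences:\n")
  print(x$excursion_differences)
  invisible(x)
}

#' Serialise a cohort summary to JSON
#'
#' @param summary A `cohort_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  jsonlite::write_json(
    lapply(unclass(summary), function(tb) as.data.frame(tb)),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Mean of the folded normal |N(mu, sigma)|
#'
#' Expected absolute value of a Gaussian: the asymptotic value of the mean
#' inter-finger delay when the true per-event offset is `mu` with Gaussian
#' jitter `sigma`. Used by the parameter-recovery harness as the
#' closed-form target for `sa_mean`.
#'
#' @param mu Offset mean in seconds.
#' @param sigma Offset standard deviation in seconds (>= 0).
#' @return `E|X|` for `X ~ N(mu, sigma)`.
#' @export
folded_normal_mean <- function(mu, sigma) {
  if (sigma < 0) abort_domain("sigma must be >= 0")
  if (sigma == 0) return(abs(mu))
  sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
}
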