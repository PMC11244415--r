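# Published reference values from the original 30-participant tapping-test
# study that this package's measurement pipeline reproduces. They serve as
# inputs for re-deriving the cohort-level statistics (mean placement CV,
# Sample Fatigue Percentage) without access to the raw recordings, which
# were not released.

#' Reference per-participant placement CVs
#'
#' Coefficients of variation of the tap count over five repeated
#' executions, for ten participants and two sensor placements: `A`
#' (intermediate phalanx) and `B` (distal phalanx, the placement the
#' protocol adopted because it perturbs the measurement less).
#'
#' @return A tibble with columns `participant` (1..10), `cv_A`, `cv_B`
#'   (percent).
#' @export
reference_placement_cvs <- function() {
  tibble::tibble(
    participant = 1:10,
    cv_A = c(10.60, 3.31, 6.16, 8.58, 3.27, 7.40, 4.54, 5.05, 5.03, 1.71),
    cv_B = c(7.40, 4.54, 5.05, 5.03, 1.71, 5.53, 4.91, 4.61, 2.76, 0.78)
  )
}

#' Reference cohort fatigue-slope distributions
#'
#' Mean and sample standard deviation of the per-participant fatigue
#' slopes (inter-tap time vs execution time, s/s) reported for each test
#' and finger of the reference cohort. Feeding each row to
#' [sample_fatigue_percentage()] reproduces the published per-cell SFP
#' values (up to the rounding of the published inputs).
#'
#' @return A tibble with columns `test_type`, `finger`, `mu`, `sigma`.
#' @export
reference_slope_distributions <- function() {
  tibble::tibble(
    test_type = c("UniSIM", "UniSIM", "UniALT", "UniALT",
                  "BimSIM", "BimSIM", "BimALT", "BimALT"),
    finger = c("index_dom", "middle_dom", "index_dom", "middle_dom",
               "index_right", "index_left", "index_right", "index_left"),
    mu = c(-0.006, -0.005, 0.006, 0.000, -0.0022, -0.0033, 0.000, -0.001),
    sigma = c(0.010, 0.010, 0.060, 0.033, 0.0075, 0.0062, 0.013, 0.017)
  )
}
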