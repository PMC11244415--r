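test_that("coefficient of variation matches hand arithmetic and is scale invariant", {
  expect_equal(coefficient_of_variation(c(10, 10, 10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(48, 50, 52)), 4, tolerance = 1e-12)
  x <- c(48, 50, 52, 47, 55)
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(50), class = "tapmetrics_insufficient_events_error")
  expect_error(coefficient_of_variation(c(0, 0)), class = "tapmetrics_domain_error")
})

test_that("mean CV over the reference placement table reproduces the published means", {
  ref <- reference_placement_cvs()
  expect_equal(round(mean_cv(ref$cv_A), 2), 5.57)
  expect_equal(round(mean_cv(ref$cv_B), 2), 4.23)
  expect_equal(mean_cv(7), 7)
  expect_error(mean_cv(numeric(0)), class = "tapmetrics_domain_error")
})

test_that("slope distribution fitting uses sample moments", {
  d <- fit_slope_distribution(c(-0.01, 0.01))
  expect_equal(d$mu, 0)
  expect_equal(d$sigma, sqrt(2) * 0.01, tolerance = 1e-10)
  expect_false(d$degenerate)

  const <- fit_slope_distribution(rep(0.02, 5))
  expect_true(const$degenerate)
  expect_equal(sample_fatigue_percentage(const), 1) # point mass above zero

  expect_error(fit_slope_distribution(0.01), class = "tapmetrics_insufficient_events_error")

  withr::with_seed(600, big <- rnorm(10000, 0.006, 0.060))
  fitted <- fit_slope_distribution(big)
  expect_lt(abs(fitted$mu - 0.006), 0.002)
})

test_that("SFP reproduces the published per-cell values from the reference slope table", {
  ref <- reference_slope_distributions()
  sfp <- vapply(seq_len(nrow(ref)), function(i) {
    sample_fatigue_percentage(slope_distribution(ref$mu[i], ref$sigma[i]))
  }, numeric(1))
  names(sfp) <- paste(ref$test_type, ref$finger)
  expect_equal(round(sfp[["UniALT index_dom"]], 2), 0.54)
  expect_equal(round(sfp[["UniALT middle_dom"]], 2), 0.50)
  expect_equal(round(sfp[["UniSIM middle_dom"]], 2), 0.31)
  expect_equal(round(sfp[["BimSIM index_right"]], 2), 0.38)
  expect_equal(round(sfp[["BimSIM index_left"]], 2), 0.30)
})

test_that("SFP satisfies its analytic properties and matches Monte-Carlo", {
  for (sig in c(0.001, 0.033, 0.5)) {
    expect_equal(sample_fatigue_percentage(slope_distribution(0, sig)), 0.5)
  }
  grid <- expand.grid(mu = c(-0.05, -0.006, 0, 0.006, 0.05), sigma = c(0.01, 0.06, 0.2))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$mu[i]
    sig <- grid$sigma[i]
    expect_equal(
      sample_fatigue_percentage(slope_distribution(-mu, sig)),
      1 - sample_fatigue_percentage(slope_distribution(mu, sig)),
      tolerance = 1e-12
    )
    withr::with_seed(700 + i, draws <- rnorm(2e5, mu, sig))
    expect_lt(
      abs(sample_fatigue_percentage(slope_distribution(mu, sig)) - mean(draws > 0)),
      0.005
    )
  }
  # strictly increasing in mu at fixed sigma
  mus <- seq(-0.1, 0.1, length.out = 21)
  vals <- vapply(mus, function(m) sample_fatigue_percentage(slope_distribution(m, 0.05)),
                 numeric(1))
  expect_true(all(diff(vals) > 0))

  # degenerate sigma handling
  expect_equal(sample_fatigue_percentage(slope_distribution(-0.01, 0)), 0)
  expect_equal(sample_fatigue_percentage(slope_distribution(0.01, 0)), 1)
  expect_error(sample_fatigue_percentage(slope_distribution(0, 0)),
               class = "tapmetrics_degenerate_error")

  # empirical variant
  expect_equal(
    sample_fatigue_percentage(empirical = TRUE, slopes = c(-1, 1, 2, 3)),
    0.75
  )
})

test_that("folded normal mean matches Monte-Carlo across offsets", {
  for (i in seq_len(4)) {
    mu <- c(0, 0, 0.07, 0.02)[i]
    sig <- c(0.01, 0.05, 0.01, 0.02)[i]
    withr::with_seed(800 + i, draws <- abs(rnorm(2e5, mu, sig)))
    expect_lt(abs(folded_normal_mean(mu, sig) - mean(draws)), 0.001)
  }
  expect_equal(folded_normal_mean(0.07, 0), 0.07)
})

test_that("cohort summary has the right cells and marks sparse cells absent", {
  cfg <- session_config(detection = detection_params(min_prominence = 1))
  trials <- list()
  for (pid in 1:3) {
    for (tt in test_types()) {
      p <- synth_params(timing_jitter = 0.005, noise = 0.05,
                        offset = 0.02, offset_jitter = 0.005,
                        seed = 1000 + pid * 10 + match(tt, test_types()))
      trials <- c(trials, list(generate_trial(tt, p, sprintf("p%d", pid))$trial))
    }
  }
  res <- analyze_cohort(trials, cfg)
  s <- res$summary
  expect_equal(nrow(s$slope_distributions), 8) # 4 tests x 2 fingers
  expect_equal(sort(s$sa_aggregates$test_type), sort(test_types()))
  expect_equal(nrow(s$excursion_differences), 3) # UniALT/BimSIM/BimALT vs UniSIM
  # simultaneous trials with tiny offsets all pass; alternate at T0/2 all pass
  expect_equal(s$failure_rates$failure_rate, rep(0, 4))

  # single-participant cells are absent, not zero
  one <- res$single[res$single$participant_id == "p1", ]
  s1 <- summarize_cohort(one, res$dual[res$dual$participant_id == "p1", ])
  expect_true(all(is.na(s1$slope_distributions$sfp)))

  empty <- summarize_cohort(
    tibble::tibble(participant_id = character(), test_type = character(),
                   finger = character(), slope = numeric(), excursion_mean = numeric()),
    tibble::tibble(participant_id = character(), test_type = character(),
                   sa_mean = numeric(), sa_std = numeric(), classification = character())
  )
  expect_equal(nrow(empty$slope_distributions), 0)
  expect_equal(nrow(empty$sa_aggregates), 0)
})
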