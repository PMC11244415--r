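test_that("inter-tap times difference, attribution and conservation", {
  ts <- tap_series(c(0, 1, 2, 3), rep(1, 4))
  it <- inter_tap_times(ts)
  expect_equal(it$inter_time, c(1, 1, 1))
  expect_equal(it$event_time, c(1, 2, 3))

  it2 <- inter_tap_times(tap_series(c(0.0, 0.4, 1.0), rep(1, 3)))
  expect_equal(it2$inter_time, c(0.4, 0.6))

  # conservation: sum of inter-times equals the peak-time span, exactly
  for (s in 1:10) {
    withr::with_seed(200 + s, tt <- sort(runif(sample(5:50, 1), 0, 30)))
    it3 <- inter_tap_times(tap_series(tt, rep(1, length(tt))))
    expect_identical(sum(it3$inter_time), tt[length(tt)] - tt[1])
  }
  expect_error(inter_tap_times(tap_series(1, 1)), class = "tapmetrics_insufficient_events_error")
})

test_that("fatigue line fit is exact on a noiseless line and matches closed-form OLS", {
  t <- seq(1, 29, by = 0.5)
  y <- 0.2 + 0.01 * t
  fit <- fit_fatigue_line(t, y)
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_false(fit$degenerate)

  for (s in 1:20) {
    withr::with_seed(300 + s, {
      n <- sample(3:40, 1)
      x <- runif(n, 0, 30)
      y <- 0.25 + rnorm(1, 0, 0.02) * x + rnorm(n, 0, 0.03)
    })
    got <- fit_fatigue_line(x, y)
    want <- oracle_ols(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  }
})

test_that("degenerate fits are flagged instead of returning NaN", {
  const <- fit_fatigue_line(c(1, 2, 3, 4), rep(0.2, 4))
  expect_true(const$degenerate)
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 1)

  expect_error(fit_fatigue_line(c(1, 2), c(0.1, 0.2)),
               class = "tapmetrics_insufficient_events_error")
  expect_error(fit_fatigue_line(rep(2, 5), 1:5), class = "tapmetrics_degenerate_error")
})

test_that("fitted slope recovers the generated drift across its sign range", {
  # the inter-time is attributed to the later tap, so the noiseless fit
  # returns exactly m / (1 + m); the mean recovery stays within 0.002 of m.
  # T0 = 0.9 s keeps the interval trajectory above the generator floor for
  # the whole trial at every m in the grid.
  for (m in c(-0.02, 0, 0.02)) {
    slopes <- vapply(1:40, function(s) {
      p <- synth_params(base_interval = 0.9, drift = m, timing_jitter = 0.01,
                        noise = 0, seed = 4000 + s)
      tt <- generate_tap_times(p, 1)
      it <- inter_tap_times(tap_series(tt, rep(1, length(tt))))
      fit_fatigue_line(it$event_time, it$inter_time)$slope
    }, numeric(1))
    q <- quantile(slopes, c(0.025, 0.975))
    expect_gt(m / (1 + m), q[1] - 1e-6)
    expect_lt(m / (1 + m), q[2] + 1e-6)
    expect_lt(abs(mean(slopes) - m), 0.002)
  }
})

test_that("windowed excursion matches the biphasic construction oracle", {
  # crest +2 g, trough -1 g pulses on a zero baseline: per-tap excursion 3 g
  p <- synth_params(duration = 30, noise = 0, pulse_amplitude = 2, seed = 1)
  tt <- generate_tap_times(p, 1)
  tr <- render_trace(tt, p)
  taps <- detect_taps(tr$az, tr$timestamps, detection_params(min_prominence = 1))
  exc <- windowed_excursion(tr$az, tr$timestamps, taps, window = 5)
  expect_length(exc$window_excursions, 6) # 30 s / 5 s
  expect_equal(exc$excursion_mean, 3, tolerance = 0.01)
  expect_lt(exc$excursion_std, 0.01)

  # doubling the signal doubles the excursion exactly
  exc2 <- windowed_excursion(2 * tr$az, tr$timestamps, taps, window = 5)
  expect_equal(exc2$excursion_mean, 2 * exc$excursion_mean, tolerance = 1e-12)

  # adding a constant offset changes nothing
  exc3 <- windowed_excursion(tr$az + 0.37, tr$timestamps, taps, window = 5)
  expect_equal(exc3$window_excursions, exc$window_excursions, tolerance = 1e-12)

  expect_error(
    windowed_excursion(tr$az, tr$timestamps, tap_series(numeric(0), numeric(0))),
    class = "tapmetrics_insufficient_events_error"
  )
})

test_that("amplitude decay shows up as declining window excursions", {
  p <- synth_params(duration = 30, noise = 0, amplitude_decay = 0.1, seed = 2)
  tt <- generate_tap_times(p, 1)
  tr <- render_trace(tt, p)
  taps <- detect_taps(tr$az, tr$timestamps, detection_params(min_prominence = 0.3))
  exc <- windowed_excursion(tr$az, tr$timestamps, taps, window = 5)
  expect_true(all(diff(exc$window_excursions) < 0))
})

test_that("excursion percent difference follows its definition", {
  expect_equal(excursion_percent_difference(2, 2), 0)
  expect_equal(excursion_percent_difference(2, 1), 50)
  expect_equal(excursion_percent_difference(1, 0.7767), 22.33, tolerance = 1e-10)
  expect_error(excursion_percent_difference(0, 1), class = "tapmetrics_domain_error")
})
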