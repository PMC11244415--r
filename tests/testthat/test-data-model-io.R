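test_that("accel_trace validation rejects malformed traces with typed errors", {
  tm <- (0:119) / 120
  ok <- accel_trace(tm, rnorm(120, 0, 0.1), rnorm(120, 0, 0.1), rnorm(120, 0, 0.1))
  expect_s3_class(ok, "accel_trace")

  expect_error(accel_trace(tm[1], 0, 0, 0), class = "tapmetrics_data_error")
  expect_error(
    accel_trace(tm, numeric(119), numeric(120), numeric(120)),
    class = "tapmetrics_data_error"
  )
  bad_t <- tm
  bad_t[50] <- bad_t[48] # non-monotone
  expect_error(
    accel_trace(bad_t, numeric(120), numeric(120), numeric(120)),
    class = "tapmetrics_data_error"
  )
  irregular <- cumsum(runif(120, 1 / 150, 1 / 90))
  expect_error(
    accel_trace(irregular, numeric(120), numeric(120), numeric(120), sampling_rate = 120),
    regexp = "irregular sampling", class = "tapmetrics_data_error"
  )
  over <- numeric(120)
  over[5] <- 9
  expect_error(
    accel_trace(tm, over, numeric(120), numeric(120)),
    regexp = "full scale", class = "tapmetrics_data_error"
  )
})

test_that("trace CSV writer round-trips through the reader exactly", {
  withr::with_seed(7, {
    n <- 600
    tm <- (seq_len(n) - 1) / 120
    tr <- accel_trace(tm, rnorm(n, 0, 0.3), rnorm(n, 0, 0.3), rnorm(n, 0, 0.3),
                      finger_label = "index_left")
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path, finger_label = "index_left", sampling_rate = 120)
  expect_identical(back$timestamps, tr$timestamps)
  expect_identical(back$ax, tr$ax)
  expect_identical(back$ay, tr$ay)
  expect_identical(back$az, tr$az)
  expect_identical(back$finger_label, tr$finger_label)
})

test_that("reader handles ms time, m/s^2 units, column maps and reports missing columns", {
  n <- 240
  tm_ms <- (seq_len(n) - 1) / 120 * 1000
  df <- data.frame(t_ms = tm_ms, X = numeric(n), Y = numeric(n), Z = sin(seq_len(n) / 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)

  tr <- read_trace_csv(
    path, "index_dom",
    column_map = c(time = "t_ms", ax = "X", ay = "Y", az = "Z"),
    time_unit = "ms"
  )
  expect_equal(trace_duration(tr), (n - 1) / 120, tolerance = 1e-12)

  df2 <- df
  df2$Z <- df2$Z * 9.81
  write.csv(df2, path, row.names = FALSE)
  tr2 <- read_trace_csv(
    path, "index_dom",
    column_map = c(time = "t_ms", ax = "X", ay = "Y", az = "Z"),
    time_unit = "ms", acceleration_unit = "ms2"
  )
  expect_equal(tr2$az, tr$az, tolerance = 1e-12)

  err <- tryCatch(
    read_trace_csv(path, "index_dom"),
    tapmetrics_format_error = function(e) e
  )
  expect_s3_class(err, "tapmetrics_format_error")
  expect_match(conditionMessage(err), "time")
})

test_that("trial_record enforces the test-type finger pairing and overlap", {
  p <- synth_params(duration = 10)
  t1 <- generate_tap_times(p, 1)
  a <- render_trace(t1, p, "index_dom", 1)
  b <- render_trace(t1, p, "middle_dom", 2)
  c_ <- render_trace(t1, p, "index_left", 2)

  expect_s3_class(trial_record("p1", "UniSIM", a, b, 10), "trial_record")
  expect_error(trial_record("p1", "UniSIM", a, a, 10), class = "tapmetrics_data_error")
  expect_error(trial_record("p1", "BimSIM", a, b, 10), class = "tapmetrics_data_error")
  expect_error(trial_record("p1", "UniSIM", a, c_, 10), class = "tapmetrics_data_error")
  # overlap < 90% of the declared duration
  expect_error(trial_record("p1", "UniSIM", a, b, duration = 20),
               class = "tapmetrics_data_error")
})

test_that("metrics table writes tidy rows and re-reads to 12 significant digits", {
  withr::with_seed(11, {
    rows <- tibble::tibble(
      participant_id = rep(sprintf("p%02d", 1:30), each = 4),
      test_type = rep(test_types(), times = 30),
      sa_mean = runif(120, 0, 0.3),
      slope = rnorm(120, 0, 0.05)
    )
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(rows, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 120)
  expect_identical(names(back), names(rows))
  expect_equal(back$sa_mean, rows$sa_mean, tolerance = 1e-12)
  expect_equal(back$slope, rows$slope, tolerance = 1e-12)

  hetero <- list(list(a = 1, b = 2), list(a = 1, c = 3))
  expect_error(write_metrics_table(hetero, path), class = "tapmetrics_data_error")
})

test_that("session config round-trips through YAML", {
  cfg <- session_config(
    detection = detection_params(min_prominence = 0.8, min_separation = 0.05,
                                 smoothing_halfwidth = 2, polarity = "auto"),
    simultaneity_threshold = 0.12, excursion_window = 4
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_session_config(cfg, path)
  back <- read_session_config(path)
  expect_equal(back$simultaneity_threshold, 0.12)
  expect_equal(back$excursion_window, 4)
  expect_equal(back$detection$min_prominence, 0.8)
  expect_equal(back$detection$polarity, "auto")
  expect_error(session_config(simultaneity_threshold = -1),
               class = "tapmetrics_config_error")
})
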