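test_that("breath estimator recovers rate and amplitude of pure sinusoids", {
  fs <- 50
  e <- estimate_breath_events(sin(2 * pi * 0.25 * seq(0, 60, by = 1 / fs)), fs)
  expect_false(is_empty_stream(e))
  expect_equal(mean(e$rate), 15, tolerance = 0.5 / 15)
  expect_equal(mean(e$amplitude[-1]), 2, tolerance = 0.1 / 2)
  e2 <- estimate_breath_events(sin(2 * pi * 0.1 * seq(0, 120, by = 1 / fs)), fs)
  expect_equal(mean(e2$rate), 6, tolerance = 0.5 / 6)
})

test_that("pulse estimator recovers cardiac rates and reports no amplitude", {
  fs <- 100
  e <- estimate_pulse_events(sin(2 * pi * 1.2 * seq(0, 60, by = 1 / fs)), fs)
  expect_equal(mean(e$rate), 72, tolerance = 1 / 72)
  expect_null(e$amplitude)
  e2 <- estimate_pulse_events(sin(2 * pi * 1.0 * seq(0, 60, by = 1 / fs)), fs)
  expect_equal(mean(e2$rate), 60, tolerance = 1 / 60)
})

test_that("rate estimates are within 1 event/min across the supported bands", {
  for (f_hz in c(0.12, 0.3, 0.45)) {
    e <- estimate_breath_events(sin(2 * pi * f_hz * seq(0, 200, by = 0.02)), 50)
    expect_lt(abs(mean(e$rate) - 60 * f_hz), 1)
  }
  for (f_hz in c(0.9, 1.7, 2.6)) {
    e <- estimate_pulse_events(sin(2 * pi * f_hz * seq(0, 90, by = 0.01)), 100)
    expect_lt(abs(mean(e$rate) - 60 * f_hz), 1)
  }
})

test_that("a chirp yields monotone nondecreasing detected rates", {
  fs <- 100
  t <- seq(0, 90, by = 1 / fs)
  f0 <- 1.0
  k <- 0.01                       # 1.0 -> 1.9 Hz over 90 s
  x <- sin(2 * pi * (f0 * t + k * t^2 / 2))
  e <- estimate_pulse_events(x, fs)
  expect_gt(length(e$times), 60)
  # peak times are quantized to the sampling grid, so individual intervals
  # jitter by ~ rate^2/(60 fs); a short running mean removes it
  sm <- stats::filter(e$rate, rep(1 / 5, 5))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -0.1))
  expect_gt(e$rate[length(e$rate)], e$rate[2])
})

test_that("degenerate input yields an empty stream, not an error", {
  e <- estimate_breath_events(rep(0, 1000), 50)
  expect_true(is_empty_stream(e))
  expect_error(interpolate_events(e, "rate"), "empty event stream")
})

test_that("piecewise-constant interpolation holds the last known value", {
  e1 <- event_stream(times = 1, rate = 70)
  d1 <- interpolate_events(e1, "rate", fs_out = 50, t_start = 0, t_end = 2)
  expect_length(d1$values, 100)
  expect_true(all(d1$values == 70))

  e2 <- event_stream(times = c(0, 1), rate = c(60, 80))
  d2 <- interpolate_events(e2, "rate", fs_out = 50, t_start = 0, t_end = 2)
  expect_equal(d2$values, rep(c(60, 80), each = 50))
})

test_that("interpolation is idempotent on an already-50-Hz step series", {
  e <- event_stream(times = c(0.5, 2.1, 3.7), rate = c(60, 75, 68))
  d <- interpolate_events(e, "rate", fs_out = 50, t_start = 0, t_end = 5)
  # re-describe the sampled series as events and resample
  chg <- c(1, which(diff(d$values) != 0) + 1)
  e2 <- event_stream(times = (chg - 1) / 50, rate = d$values[chg])
  d2 <- interpolate_events(e2, "rate", fs_out = 50, t_start = 0, t_end = 5)
  expect_identical(d2$values, d$values)
})

test_that("event streams validate their invariants", {
  expect_error(event_stream(c(1, 1), c(60, 60)), "strictly increasing")
  expect_error(event_stream(c(1, 2), 60), "length")
})
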