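test_that("moving mean handles constants, ramps and full-period sines", {
  expect_equal(moving_mean(rep(3.5, 10), 4), rep(3.5, 10))
  # hand-computed shrinking-edge means
  expect_equal(moving_mean(c(0, 1, 2, 3, 4), 3), c(0.5, 1, 2, 3, 3.5))
  # zero-mean sine averaged over exactly one period vanishes away from edges
  fs <- 10
  x <- sin(2 * pi * 0.2 * seq(0, 30, by = 1 / fs))
  mm <- moving_mean(x, 5, fs)
  interior <- mm[51:250]
  expect_lt(max(abs(interior)), 0.01)
  expect_error(moving_mean(1:10, 20), "longer than the series")
  expect_error(moving_mean(1:10, 1), "at least 2 samples")
})

test_that("a clean sine is counted exactly: 15 cycles/min over 60 s", {
  fs <- 10
  x <- clean_breath_sine(15, 60, fs)
  # independent oracle: rising zero-crossings of the analytic signal
  n_oracle <- sum(diff(sign(x)) > 0)
  expect_equal(n_oracle, 15)
  det <- detect_breaths(x, fs)
  expect_length(det$event_times, 15)
  expect_equal(det$rate, 15)
  expect_true(all(diff(det$event_times) >= 1.5))
})

test_that("constant input yields zero events and rate 0", {
  det <- detect_breaths(rep(2, 600), 10)
  expect_length(det$event_times, 0)
  expect_equal(det$rate, 0)
})

test_that("detection is invariant to offset and amplitude rescaling", {
  fs <- 10
  x <- clean_breath_sine(12, 120, fs, amplitude = 15)
  base <- detect_breaths(x, fs, pressure_detector())
  shifted <- detect_breaths(x + 101325, fs, pressure_detector())
  scaled <- detect_breaths(2.5 * x, fs, pressure_detector())
  expect_equal(shifted$event_times, base$event_times)
  expect_equal(scaled$event_times, base$event_times)
})

test_that("detected rate recovers the simulated rate within 1 breath/min", {
  fs <- 10
  for (rate in c(6, 9, 12, 15, 20)) {
    for (seed in 1:20) {
      rec <- simulate_session(flat_scenario(120),
                              breathing_model(rate = rate),
                              seed = 7000 * rate + seed)
      dp <- detect_breaths(rec$inner$pressure, fs, pressure_detector())
      dt <- detect_breaths(rec$inner$temperature, fs,
                           temperature_detector())
      expect_lte(abs(dp$rate - rate), 1)
      expect_lte(abs(dt$rate - rate), 1)
    }
  }
})

test_that("stutters raise the pressure count above the temperature count", {
  for (seed in 1:5) {
    rec <- simulate_session(flat_scenario(120),
                            breathing_model(rate = 11, stutter_prob = 0.2),
                            seed = seed)
    dp <- detect_breaths(rec$inner$pressure, rec$sample_rate,
                         pressure_detector())
    dt <- detect_breaths(rec$inner$temperature, rec$sample_rate,
                         temperature_detector())
    expect_gte(length(dp$event_times), length(dt$event_times))
    if (rec$meta$n_stutters > 0) {
      expect_gt(length(dp$event_times), length(dt$event_times))
    }
  }
})

test_that("inner channel never under-counts the attenuated outer channel", {
  # min_amplitude set to the pressure noise floor so a breath buried in
  # noise is missed rather than fabricated
  floor_cfg <- detector_config(min_amplitude = 6 * 1.2)
  for (seed in 1:5) {
    rec <- simulate_session(flat_scenario(120),
                            breathing_model(rate = 12,
                                            outer_pressure_p2p = 1),
                            seed = 100 + seed)
    din <- detect_breaths(rec$inner$pressure, rec$sample_rate, floor_cfg)
    dout <- detect_breaths(rec$outer$pressure, rec$sample_rate, floor_cfg)
    expect_gte(din$rate, dout$rate)
    expect_lte(abs(din$rate - 12), 1)
  }
})

test_that("peak-to-peak of a pure sine is twice the amplitude", {
  fs <- 10
  x <- clean_breath_sine(12, 120, fs, amplitude = 7)
  det <- detect_breaths(x, fs)
  s <- peak_to_peak_stats(x, fs, det)
  expect_equal(s$mean, 14, tolerance = 0.01)
  empty <- peak_to_peak_stats(x, fs, list(event_times = numeric(0)))
  expect_length(empty$per_breath, 0)
  expect_true(is.na(empty$mean))
})

test_that("series shorter than twice the window is rejected", {
  expect_error(detect_breaths(rnorm(50), 10), "twice the moving-mean window")
})
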