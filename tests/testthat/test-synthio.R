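test_that("identical inputs give bit-identical records", {
  a <- simulate_session(flat_scenario(60), seed = 11)
  b <- simulate_session(flat_scenario(60), seed = 11)
  expect_identical(a, b)
  c <- simulate_session(flat_scenario(60), seed = 12)
  expect_false(identical(a$inner$pressure, c$inner$pressure))
})

test_that("a 2-min session at 11 breaths/min carries 22 +/- 1 pressure cycles", {
  rec <- simulate_session(flat_scenario(120, ambient_temp = 23),
                          breathing_model(rate = 11), seed = 1)
  det <- detect_breaths(rec$inner$pressure, rec$sample_rate,
                        pressure_detector())
  expect_gte(length(det$event_times), 21)
  expect_lte(length(det$event_times), 23)
})

test_that("zero excitation and zero noise give flat series at baselines", {
  ctl <- sim_control(temp_noise_sd = 0, pressure_noise_sd = 0,
                     humidity_noise_sd = 0, gas_noise_sd = 0, bias = FALSE)
  bm <- breathing_model(inner_pressure_p2p = 1e-12, outer_pressure_p2p = 0,
                        inner_temp_p2p = 0)
  rec <- simulate_session(flat_scenario(60, ambient_temp = 23), bm,
                          seed = 4, control = ctl)
  expect_equal(unique(rec$inner$pressure), 101325, tolerance = 0.2)
  expect_lt(diff(range(rec$inner$pressure)), 0.2)
  expect_equal(unique(rec$outer$temperature), 23, tolerance = 0.02)
  expect_lt(diff(range(rec$outer$temperature)), 0.02)
})

test_that("a two-floor ascent drops the outer baseline by ~115 Pa", {
  ctl <- sim_control(temp_noise_sd = 0, pressure_noise_sd = 0,
                     humidity_noise_sd = 0, bias = FALSE)
  bm <- breathing_model(inner_pressure_p2p = 1e-12, outer_pressure_p2p = 0,
                        inner_temp_p2p = 0)
  rec <- simulate_session(stair_scenario(2), bm, seed = 1, control = ctl)
  drop <- rec$outer$pressure[length(rec$time)] - rec$outer$pressure[1]
  expect_equal(drop, -115, tolerance = 0.5)
})

test_that("simulated peak-to-peak amplitudes match the field bands", {
  rec <- simulate_session(flat_scenario(300), seed = 7)
  fs <- rec$sample_rate
  din <- detect_breaths(rec$inner$pressure, fs, pressure_detector())
  expect_gt(peak_to_peak_stats(rec$inner$pressure, fs, din)$mean, 20)
  expect_lt(peak_to_peak_stats(rec$inner$pressure, fs, din)$mean, 40)
  dout <- detect_breaths(rec$outer$pressure, fs, pressure_detector())
  expect_lt(peak_to_peak_stats(rec$outer$pressure, fs, dout)$mean, 10)
  dt <- detect_breaths(rec$inner$temperature, fs, temperature_detector())
  expect_lte(peak_to_peak_stats(rec$inner$temperature, fs, dt)$mean, 1)
})

test_that("temperature lags pressure by temp_lag within one sample", {
  for (seed in c(3, 8)) {
    rec <- simulate_session(flat_scenario(300), seed = seed)
    fs <- rec$sample_rate
    pt <- rec$inner$temperature - moving_mean(rec$inner$temperature, 5, fs)
    pp <- rec$inner$pressure - moving_mean(rec$inner$pressure, 5, fs)
    period <- round(60 / rec$meta$breathing$rate * fs)
    cc <- stats::ccf(pt, pp, lag.max = period - 1, plot = FALSE)
    lags <- cc$lag[, 1, 1]
    pos <- lags >= 0
    peak <- lags[pos][which.max(cc$acf[pos])]
    expect_equal(peak, rec$meta$breathing$temp_lag * fs, tolerance = 1.01)
  }
})

test_that("all channels are quantized to the sensor resolutions", {
  rec <- simulate_session(flat_scenario(90), seed = 2)
  mult_of <- function(x, res) max(abs(x / res - round(x / res))) < 1e-6
  spec <- rec$meta$spec
  expect_true(mult_of(rec$inner$temperature, spec$temp_resolution))
  expect_true(mult_of(rec$outer$temperature, spec$temp_resolution))
  expect_true(mult_of(rec$inner$pressure, spec$pressure_resolution))
  expect_true(mult_of(rec$outer$pressure, spec$pressure_resolution))
  expect_true(mult_of(rec$inner$humidity, spec$humidity_resolution))
})

test_that("saturation profile is monotone, bounded, and hits the window", {
  expect_equal(saturation_profile(0), 40)
  expect_gte(saturation_profile(30 * 60, time_constant = 550), 95)
  h <- saturation_profile(seq(0, 7200, by = 10), time_constant = 550)
  expect_true(all(diff(h) >= 0))
  expect_lte(max(h), 100)
  expect_error(saturation_profile(-1), "non-negative")
})

test_that("invalid scenarios and parameters are rejected", {
  expect_error(scenario_segment("street", -10), "positive")
  expect_error(scenario_segment("street", 60, pressure_baseline = 200000),
               "\\[30000, 110000\\]")
  expect_error(breathing_model(rate = 0), "positive")
  expect_error(breathing_model(inner_pressure_p2p = 5,
                               outer_pressure_p2p = 10),
               "must exceed")
  expect_error(simulate_session(flat_scenario(60)), "seed")
  short <- scenario_script(
    scenario_segment("stairs", 15, floor_delta = 3,
                     pressure_baseline = 101325))
  expect_error(simulate_session(short, seed = 1), "too short")
})

test_that("AQI stays in range and accuracy follows the settling schedule", {
  rec <- simulate_session(demo_scenario(), seed = 3)
  expect_true(all(rec$outer$aqi >= 0 & rec$outer$aqi <= 500))
  expect_true(all(rec$outer$aqi_accuracy %in% 0:3))
  acc <- rec$outer$aqi_accuracy
  expect_true(all(diff(acc) >= 0))
  tcfg <- rec$meta$control$accuracy_times
  expect_equal(min(rec$time[acc >= 2]), tcfg[2], tolerance = 0.2)
})
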