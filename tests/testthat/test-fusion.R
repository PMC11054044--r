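test_that("drift rate is exact on ramps and null on constants and sines", {
  fs <- 10
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  expect_equal(drift_rate(0.2 / 60 * t, fs), 0.2, tolerance = 1e-10)
  expect_equal(drift_rate(rep(5, 600), fs), 0)
  # zero-mean breath sine on a flat baseline barely registers
  x <- 0.4 * sin(2 * pi * 0.2 * t)
  expect_lt(abs(drift_rate(x, fs)), 0.02)
  expect_error(drift_rate(1:100, 10, window = 60), "longer than the series")
})

test_that("source selection follows the drift rule", {
  expect_equal(select_source(0.05, 5), "TEMPERATURE")
  expect_equal(select_source(0.5, 5), "PRESSURE")
  expect_equal(select_source(0.5, 60), "PAUSED")
  expect_equal(select_source(-0.5, -60), "PAUSED")  # absolute values
  expect_equal(select_source(0.1, 5), "TEMPERATURE")  # boundary inclusive
  expect_error(select_source(NaN, 1), "finite")
})

test_that("PAUSED occurs iff both drifts exceed their thresholds", {
  cfg <- fusion_config()
  for (td in c(0.01, 0.09, 0.3, 2)) {
    for (pd in c(1, 25, 45, 80)) {
      s <- select_source(td, pd, cfg)
      both <- abs(td) > cfg$temp_drift_threshold &&
        abs(pd) > cfg$pressure_baseline_threshold
      expect_identical(s == "PAUSED", both)
    }
  }
})

test_that("flat ambience keeps the temperature source throughout", {
  rec <- simulate_session(flat_scenario(300), seed = 2)
  fr <- fused_respiration(rec)
  expect_true(all(fr$source == "TEMPERATURE"))
  expect_false(any(fr$waiting))
  expect_true(all(abs(fr$rate - rec$meta$breathing$rate) <= 1))
})

test_that("an ambient temperature step switches to pressure, rate intact", {
  ww <- scenario_script(
    scenario_segment("street", 300, ambient_temp = 22, ambient_aqi = 70,
                     pressure_baseline = 101325),
    scenario_segment("indoors", 300, ambient_temp = 32, ambient_aqi = 120),
    scenario_segment("street", 300, ambient_temp = 22, ambient_aqi = 70),
    name = "winter-walk")
  rec <- simulate_session(ww, breathing_model(rate = 12), seed = 5)
  fr <- fused_respiration(rec)
  expect_true(any(fr$source == "PRESSURE"))
  # windows spanning the steps choose pressure
  step_windows <- fr$t_start <= 300 & fr$t_end >= 330
  expect_true(all(fr$raw_source[step_windows] == "PRESSURE"))
  expect_false(any(fr$waiting))
  expect_true(all(abs(fr$rate[!fr$waiting] - 12) <= 1))
})

test_that("simultaneous temperature step and continuous climb pauses", {
  ps <- scenario_script(
    scenario_segment("indoors", 120, ambient_temp = 22, ambient_aqi = 80,
                     pressure_baseline = 102480),
    scenario_segment("stairs", 120, ambient_temp = 32, ambient_aqi = 80,
                     floor_delta = 8),
    scenario_segment("indoors", 120, ambient_temp = 32, ambient_aqi = 80),
    name = "pause-case")
  rec <- simulate_session(ps, seed = 5, control = sim_control(stair_pause = 2))
  fr <- fused_respiration(rec)
  expect_true(any(fr$waiting))
  expect_true(all(is.na(fr$rate[fr$waiting])))
})

test_that("one story transition alone never pauses and breath band never trips", {
  rec <- simulate_session(stair_scenario(1), seed = 9)
  fr <- fused_respiration(rec)
  expect_false(any(fr$raw_source == "PAUSED"))
  # breath dynamics on a flat walk stay far below the baseline threshold
  flat <- simulate_session(flat_scenario(300), seed = 10)
  ff <- fused_respiration(flat)
  expect_lt(max(abs(ff$pressure_drift)), fusion_config()$pressure_baseline_threshold / 3)
})

test_that("pressure-source decisions ignore global temperature offsets", {
  ww <- scenario_script(
    scenario_segment("street", 180, ambient_temp = 22, pressure_baseline = 101325),
    scenario_segment("indoors", 180, ambient_temp = 32),
    name = "step")
  rec <- simulate_session(ww, seed = 6)
  fr1 <- fused_respiration(rec)
  rec$inner$temperature <- rec$inner$temperature + 5
  fr2 <- fused_respiration(rec)
  expect_equal(fr1$raw_source, fr2$raw_source)
  expect_equal(fr1$pressure_drift, fr2$pressure_drift)
})

test_that("records shorter than one evaluation window are rejected", {
  rec <- simulate_session(flat_scenario(30), seed = 1)
  expect_error(fused_respiration(rec), "shorter than one evaluation window")
})
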