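test_that("AQI classes partition [0, 500] and are monotone", {
  expect_equal(as.character(classify_aqi(25)), "excellent")
  expect_equal(as.character(classify_aqi(75)), "good")
  expect_equal(as.character(classify_aqi(400)), "extremely polluted")
  # the printed-table overlap resolves to contiguous classes at 250/251/350/351
  expect_equal(as.character(classify_aqi(c(250, 251, 350, 351))),
               c("heavily polluted", "severely polluted",
                 "severely polluted", "extremely polluted"))
  v <- seq(0, 500, by = 0.5)
  cls <- classify_aqi(v)
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
  tab <- aqi_classes()
  expect_equal(tab$lower[-1], tab$upper[-nrow(tab)] + 1)
  expect_error(classify_aqi(501), "\\[0, 500\\]")
  expect_error(classify_aqi(-1), "\\[0, 500\\]")
})

test_that("accuracy gating partitions samples and reports settling time", {
  s <- data.frame(time = c(0, 10, 20, 30), value = c(10, 20, 30, 40),
                  accuracy = c(0, 1, 2, 3))
  g <- gate_by_accuracy(s)
  expect_equal(g$samples$reliable, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(g$time_to_reliability, 20)
  all3 <- gate_by_accuracy(transform(s, accuracy = 3))
  expect_true(all(all3$samples$reliable))
  none <- gate_by_accuracy(transform(s, accuracy = 0))
  expect_false(any(none$samples$reliable))
  expect_equal(none$time_to_reliability, Inf)
  # degenerate gate marks everything reliable
  expect_true(all(gate_by_accuracy(s, min_status = 0)$samples$reliable))
})

test_that("simulated sessions become AQI-reliable only after half an hour", {
  rec <- simulate_session(demo_scenario(), seed = 4)
  g <- gate_by_accuracy(aqi_samples(rec))
  expect_gt(g$time_to_reliability, 30 * 60)
})

test_that("humidity invalidation lands in the 20-30 min window", {
  rec <- simulate_session(demo_scenario(), seed = 6)
  h <- humidity_validity(rec$inner$humidity, rec$sample_rate)
  expect_true(h$invalid)
  expect_gt(h$invalid_from, 20 * 60)
  expect_lt(h$invalid_from, 30 * 60)
})

test_that("constant humidity stays valid; brief spikes do not invalidate", {
  ok <- humidity_validity(rep(40, 1200), 10)
  expect_false(ok$invalid)
  spiky <- rep(40, 1200)
  spiky[600] <- 96
  expect_false(humidity_validity(spiky, 10)$invalid)
  sat <- c(rep(40, 300), rep(97, 900))
  r <- humidity_validity(sat, 10)
  expect_true(r$invalid)
  expect_equal(r$invalid_from, 30)
})

test_that("a flat session yields a single zone segment", {
  rec <- simulate_session(flat_scenario(600), seed = 2)
  z <- segment_zones(rec$outer$temperature, rec$sample_rate,
                     aqi = aqi_samples(rec))
  expect_equal(nrow(z), 1)
  expect_equal(z$start, 0)
  expect_equal(z$end, 600)
})

test_that("street-shop-street boundaries are found within two windows", {
  sc <- scenario_script(
    scenario_segment("street", 600, ambient_temp = 22, ambient_aqi = 70,
                     pressure_baseline = 101325),
    scenario_segment("shop", 600, ambient_temp = 29, ambient_aqi = 150),
    scenario_segment("street", 600, ambient_temp = 22, ambient_aqi = 70),
    name = "street-shop-street")
  rec <- simulate_session(sc, seed = 8)
  z <- segment_zones(rec$outer$temperature, rec$sample_rate,
                     aqi = aqi_samples(rec))
  expect_equal(nrow(z), 3)
  w <- zone_config()$window
  expect_lt(abs(z$end[1] - 600), 2 * w)
  expect_lt(abs(z$end[2] - 1200), 2 * w)
  expect_equal(z$label, c("outdoor", "indoor", "outdoor"))
})

test_that("segments tile the session and zones label the demo walk", {
  rec <- simulate_session(demo_scenario(), seed = 1)
  z <- segment_zones(rec$outer$temperature, rec$sample_rate,
                     aqi = aqi_samples(rec))
  expect_equal(z$start[-1], z$end[-nrow(z)])
  expect_equal(z$start[1], 0)
  expect_equal(z$end[nrow(z)], length(rec$time) / rec$sample_rate)
  expect_true("indoor" %in% z$label && "outdoor" %in% z$label)
  expect_true("transit" %in% z$label)  # the bus leg: warm-ish, elevated AQI
})

test_that("post-calibration street AQI sits in the scripted 50-100 band", {
  rec <- simulate_session(demo_scenario(), seed = 3)
  g <- gate_by_accuracy(aqi_samples(rec))
  segs <- rec$meta$script$segments
  street_late <- segs$label == "street" &
    segs$t_start > g$time_to_reliability
  expect_true(any(street_late))
  for (k in which(street_late)) {
    idx <- rec$time >= segs$t_start[k] + 120 & rec$time < segs$t_end[k]
    expect_gt(mean(rec$outer$aqi[idx]), 50)
    expect_lt(mean(rec$outer$aqi[idx]), 100)
  }
})

test_that("unreliable AQI never creates zone boundaries", {
  sc <- scenario_script(
    scenario_segment("street", 300, ambient_temp = 22, ambient_aqi = 20,
                     pressure_baseline = 101325),
    scenario_segment("street", 300, ambient_temp = 22, ambient_aqi = 200),
    scenario_segment("street", 300, ambient_temp = 22, ambient_aqi = 20),
    name = "aqi-only-steps")
  # all AQI steps happen before calibration: no boundaries may appear
  rec <- simulate_session(sc, seed = 11)
  z <- segment_zones(rec$outer$temperature, rec$sample_rate,
                     aqi = aqi_samples(rec))
  expect_equal(nrow(z), 1)
})
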