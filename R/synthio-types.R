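#' Sensor specification
#'
#' Resolution and accuracy figures of the environmental sensor cluster used on
#' both sides of the mask. Defaults are the datasheet values of the BME680
#' class of sensors: 0.01 degC temperature resolution with +/-0.5 degC absolute
#' accuracy, 0.18 Pa pressure resolution with +/-12 Pa relative accuracy,
#' 0.008 %rh humidity resolution with +/-3 %rh absolute accuracy, and a
#' +/-1.3 Pa/K pressure temperature-coefficient offset.
#'
#' @param temp_resolution Temperature output resolution (degC).
#' @param temp_abs_accuracy Absolute temperature accuracy bound (degC).
#' @param pressure_resolution Pressure output resolution (Pa).
#' @param pressure_rel_accuracy Relative pressure accuracy bound (Pa).
#' @param humidity_resolution Humidity output resolution (%rh).
#' @param humidity_abs_accuracy Absolute humidity accuracy bound (%rh).
#' @param pressure_temp_coeff Pressure temperature coefficient (Pa/K).
#' @return An object of class `sensor_spec`.
#' @export
#' @examples
#' sensor_spec()
sensor_spec <- function(temp_resolution = 0.01,
                        temp_abs_accuracy = 0.5,
                        pressure_resolution = 0.18,
                        pressure_rel_accuracy = 12,
                        humidity_resolution = 0.008,
                        humidity_abs_accuracy = 3,
                        pressure_temp_coeff = 1.3) {
  spec <- list(temp_resolution = temp_resolution,
               temp_abs_accuracy = temp_abs_accuracy,
               pressure_resolution = pressure_resolution,
               pressure_rel_accuracy = pressure_rel_accuracy,
               humidity_resolution = humidity_resolution,
               humidity_abs_accuracy = humidity_abs_accuracy,
               pressure_temp_coeff = pressure_temp_coeff)
  for (nm in names(spec)) assert_scalar_num(spec[[nm]], nm, positive = TRUE)
  structure(spec, class = "sensor_spec")
}

#' Breathing model
#'
#' Parameters of the simulated respiration signal. Defaults reflect field
#' characterizations of in-mask recordings: inner pressure peak-to-peak in the
#' 20-40 Pa band, outer pressure peak-to-peak below 10 Pa, inner temperature
#' peak-to-peak within 1 degC, and a ~3 s thermal lag of temperature behind
#' pressure caused by the sensor's thermal inertia.
#'
#' @param rate Respiration rate (breaths/min). Must be > 0.
#' @param inner_pressure_p2p Inner-channel breath pressure peak-to-peak (Pa).
#' @param outer_pressure_p2p Outer-channel breath pressure peak-to-peak (Pa);
#'   must be smaller than the inner value (the mask attenuates the breath
#'   signal seen by the outward-facing sensor).
#' @param inner_temp_p2p Inner-channel breath temperature peak-to-peak (degC).
#' @param temp_lag Lag of the temperature oscillation behind pressure (s).
#' @param waveform `"sinusoid"` (default) or `"asymmetric"` (faster exhale).
#' @param stutter_prob Probability per breath of a split/minor sub-peak that is
#'   visible in pressure but smoothed away by thermal inertia in temperature.
#' @return An object of class `breathing_model`.
#' @export
#' @examples
#' breathing_model(rate = 11, stutter_prob = 0.2)
breathing_model <- function(rate = 12,
                            inner_pressure_p2p = 30,
                            outer_pressure_p2p = 5,
                            inner_temp_p2p = 0.8,
                            temp_lag = 3,
                            waveform = c("sinusoid", "asymmetric"),
                            stutter_prob = 0) {
  waveform <- match.arg(waveform)
  assert_scalar_num(rate, "rate", positive = TRUE)
  assert_scalar_num(inner_pressure_p2p, "inner_pressure_p2p", positive = TRUE)
  assert_scalar_num(outer_pressure_p2p, "outer_pressure_p2p", nonneg = TRUE)
  if (outer_pressure_p2p >= inner_pressure_p2p) {
    stop("`inner_pressure_p2p` must exceed `outer_pressure_p2p`",
         call. = FALSE)
  }
  assert_scalar_num(inner_temp_p2p, "inner_temp_p2p", nonneg = TRUE)
  assert_scalar_num(temp_lag, "temp_lag", nonneg = TRUE)
  assert_scalar_num(stutter_prob, "stutter_prob", lower = 0, upper = 1)
  structure(list(rate = rate,
                 inner_pressure_p2p = inner_pressure_p2p,
                 outer_pressure_p2p = outer_pressure_p2p,
                 inner_temp_p2p = inner_temp_p2p,
                 temp_lag = temp_lag,
                 waveform = waveform,
                 stutter_prob = stutter_prob),
            class = "breathing_model")
}

#' Scenario scripts
#'
#' A scenario script is an ordered list of segments describing an urban
#' session: each segment has a label, a duration, the temperature the mask
#' sensors settle to, an ambient AQI level, an optional floor transition
#' (stairs) and an optional barometric baseline. Unset baselines (`NA`) carry
#' the running baseline forward, which is what stairs segments modify.
#'
#' @param label Segment label: `"street"`, `"shop"`, `"bus"`, `"indoors"`,
#'   `"stairs"` or `"custom"`.
#' @param duration Segment duration (s), strictly positive.
#' @param ambient_temp Temperature the sensors settle toward (degC).
#' @param ambient_aqi Ambient AQI level of the segment (0-500).
#' @param floor_delta Signed number of floors climbed during the segment
#'   (positive = ascent); non-zero only makes sense for stairs segments.
#' @param pressure_baseline Barometric baseline (Pa) or `NA` to continue the
#'   previous segment's baseline. Must lie within the 300-1100 hPa sensor
#'   range when given.
#' @return `scenario_segment()` returns a one-row data frame;
#'   `scenario_script()` an object of class `scenario_script` whose
#'   `$segments` data frame carries computed `t_start`/`t_end` columns.
#' @export
#' @examples
#' scenario_script(
#'   scenario_segment("street", 120, ambient_temp = 22, ambient_aqi = 70),
#'   scenario_segment("stairs", 60, ambient_temp = 24, floor_delta = 2)
#' )
scenario_segment <- function(label = c("street", "shop", "bus", "indoors",
                                       "stairs", "custom"),
                             duration,
                             ambient_temp = 22,
                             ambient_aqi = 50,
                             floor_delta = 0,
                             pressure_baseline = NA_real_) {
  label <- match.arg(label)
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(ambient_temp, "ambient_temp")
  assert_scalar_num(ambient_aqi, "ambient_aqi", lower = 0, upper = 500)
  assert_scalar_num(floor_delta, "floor_delta")
  if (floor_delta != round(floor_delta)) {
    stop("`floor_delta` must be an integer number of floors", call. = FALSE)
  }
  if (!is.na(pressure_baseline)) {
    assert_scalar_num(pressure_baseline, "pressure_baseline",
                      lower = 30000, upper = 110000)
  }
  data.frame(label = label, duration = duration,
             ambient_temp = ambient_temp, ambient_aqi = ambient_aqi,
             floor_delta = as.integer(floor_delta),
             pressure_baseline = as.numeric(pressure_baseline))
}

#' @rdname scenario_segment
#' @param ... For `scenario_script()`: segments created by
#'   `scenario_segment()` (or a single data frame with the same columns).
#' @param name Optional scenario name stored with the script.
#' @export
scenario_script <- function(..., name = "custom") {
  segs <- list(...)
  if (length(segs) == 1L && is.data.frame(segs[[1]]) &&
      !("duration" %in% names(segs)[1])) {
    segments <- segs[[1]]
  } else {
    segments <- do.call(rbind, segs)
  }
  if (is.null(segments) || nrow(segments) == 0L) {
    stop("a scenario script needs at least one segment", call. = FALSE)
  }
  needed <- c("label", "duration", "ambient_temp", "ambient_aqi",
              "floor_delta", "pressure_baseline")
  if (!all(needed %in% names(segments))) {
    stop("segments must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(segments$duration <= 0)) {
    stop("segment durations must be strictly positive", call. = FALSE)
  }
  pb <- segments$pressure_baseline
  if (any(!is.na(pb) & (pb < 30000 | pb > 110000))) {
    stop("pressure baselines must lie within 300-1100 hPa", call. = FALSE)
  }
  segments$t_end <- cumsum(segments$duration)
  segments$t_start <- segments$t_end - segments$duration
  rownames(segments) <- NULL
  structure(list(name = name, segments = segments), class = "scenario_script")
}

#' @export
print.scenario_script <- function(x, ...) {
  cat(sprintf("<scenario_script '%s': %d segments, %.0f s total>\n",
              x$name, nrow(x$segments), sum(x$segments$duration)))
  print(x$segments[, c("label", "duration", "ambient_temp", "ambient_aqi",
                       "floor_delta", "pressure_baseline")])
  invisible(x)
}

#' Ready-made scenario scripts
#'
#' `demo_scenario()` is a ~55 min winter urban walk with street, shop, bus,
#' stairs and indoor segments (temperature settling near 22-23 degC on the
#' street and near 30 degC indoors, AQI degrading in the shop and on the bus).
#' `stair_scenario()` is a short indoor session whose middle segment climbs a
#' given number of floors. `flat_scenario()` is a single steady segment,
#' useful for respiration-only analyses.
#'
#' @param floors Signed number of floors for `stair_scenario()`.
#' @param duration Duration (s) of the single segment of `flat_scenario()`.
#' @param ambient_temp,ambient_aqi Conditions of the flat segment.
#' @return A `scenario_script`.
#' @export
demo_scenario <- function() {
  scenario_script(
    scenario_segment("street", 900, ambient_temp = 22, ambient_aqi = 70,
                     pressure_baseline = 102480),
    scenario_segment("shop", 600, ambient_temp = 29, ambient_aqi = 200),
    scenario_segment("street", 480, ambient_temp = 22, ambient_aqi = 70),
    scenario_segment("bus", 600, ambient_temp = 25, ambient_aqi = 170),
    scenario_segment("street", 300, ambient_temp = 22, ambient_aqi = 70),
    scenario_segment("stairs", 120, ambient_temp = 26.5, ambient_aqi = 90,
                     floor_delta = 2),
    scenario_segment("indoors", 300, ambient_temp = 29, ambient_aqi = 120),
    name = "urban-walk-demo"
  )
}

#' @rdname demo_scenario
#' @export
stair_scenario <- function(floors = 2) {
  scenario_script(
    scenario_segment("indoors", 60, ambient_temp = 24, ambient_aqi = 80,
                     pressure_baseline = 102480),
    scenario_segment("stairs", 90, ambient_temp = 24, ambient_aqi = 80,
                     floor_delta = floors),
    scenario_segment("indoors", 60, ambient_temp = 24, ambient_aqi = 80),
    name = sprintf("stairs-%+d", floors)
  )
}

#' @rdname demo_scenario
#' @export
flat_scenario <- function(duration = 120, ambient_temp = 23,
                          ambient_aqi = 60) {
  scenario_script(
    scenario_segment("street", duration, ambient_temp = ambient_temp,
                     ambient_aqi = ambient_aqi,
                     pressure_baseline = 101325),
    name = "flat"
  )
}
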