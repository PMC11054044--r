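#' Atmosphere model for barometric altimetry
#'
#' Reference state for converting pressure differences to height differences.
#' The device has an uncalibrated absolute offset (mask embedding and thermal
#' effects), so only relative heights against `reference_pressure` are
#' meaningful.
#'
#' @param reference_pressure Reference pressure (Pa), within the 300-1100 hPa
#'   sensor range; sea-level standard pressure 101,325 Pa by default.
#' @param reference_temperature Air temperature (K); 288.15 K standard
#'   atmosphere by default (the outer, ambient-facing sensor drives
#'   altimetry, not the in-mask temperature).
#' @param gas_constant_dry_air Specific gas constant of dry air (J/(kg K)).
#' @param gravity Gravitational acceleration (m/s^2).
#' @return A list of class `atmosphere_model`.
#' @export
atmosphere_model <- function(reference_pressure = 101325,
                             reference_temperature = 288.15,
                             gas_constant_dry_air = 287.05,
                             gravity = 9.80665) {
  assert_scalar_num(reference_pressure, "reference_pressure",
                    lower = 30000, upper = 110000)
  assert_scalar_num(reference_temperature, "reference_temperature",
                    positive = TRUE)
  assert_scalar_num(gas_constant_dry_air, "gas_constant_dry_air",
                    positive = TRUE)
  assert_scalar_num(gravity, "gravity", positive = TRUE)
  structure(list(reference_pressure = reference_pressure,
                 reference_temperature = reference_temperature,
                 gas_constant_dry_air = gas_constant_dry_air,
                 gravity = gravity),
            class = "atmosphere_model")
}

#' Convert pressure to height relative to a reference
#'
#' Linearized hypsometric relation: `dh = (p_ref - p) / (rho * g)` with the
#' air density `rho = p_mid / (R_d * T)` evaluated at the mean of `p` and the
#' reference pressure. Lower pressure maps to higher altitude. Over building
#' scales (|dp| <= 200 Pa) this agrees with the log-form barometric formula
#' to better than 0.1%; a 55-60 Pa per-floor drop converts to a 4.5-5 m story
#' height at standard temperature.
#'
#' @param p Pressure (Pa); vectorized. Must lie within 300-1100 hPa.
#' @param atm An [atmosphere_model()].
#' @return Height (m) relative to the reference pressure level;
#'   `pressure_to_height(p_ref) == 0`.
#' @export
#' @examples
#' pressure_to_height(102420, atmosphere_model(102480))  # ~4.94 m
pressure_to_height <- function(p, atm = atmosphere_model()) {
  if (any(!is.finite(p)) || any(p < 30000 | p > 110000)) {
    stop("pressure outside the 300-1100 hPa sensor range", call. = FALSE)
  }
  p_mid <- (p + atm$reference_pressure) / 2
  rho <- p_mid / (atm$gas_constant_dry_air * atm$reference_temperature)
  (atm$reference_pressure - p) / (rho * atm$gravity)
}

#' Detect floor transitions in a barometric series
#'
#' Finds baseline shifts consistent with story transitions (~55-60 Pa over
#' ~10 s per floor) while ignoring the breath-band oscillation. The series is
#' first smoothed with a short moving mean to remove the breath band; a
#' centered difference of the smoothed baseline over a `window`-second span is
#' then thresholded, and each above-threshold run yields one event at the
#' extremum of the shift, converted to a height change with
#' [pressure_to_height()] (ascent, i.e. a pressure drop, is positive).
#'
#' @param pressure Uniformly sampled pressure series (Pa); typically the
#'   outer channel, whose breath amplitude is small.
#' @param fs Sampling rate (Hz).
#' @param threshold Baseline-shift threshold (Pa) for an event; the default
#'   40 Pa is above the breath band and below the one-floor signature.
#' @param window Span (s) of the centered baseline difference; must cover one
#'   full ramp plus smoothing (default 15 s) yet stay below the spacing of
#'   consecutive flights so separate floors remain distinct events.
#' @param smooth_window Breath-band-removal moving-mean window (s).
#' @param atm Optional [atmosphere_model()] supplying temperature and
#'   constants; its reference pressure is overridden per event by the
#'   pre-event baseline.
#' @return A data frame of class `floor_events` with one row per event:
#'   `time` (s), `dp` (Pa, signed baseline shift) and `dheight` (m, positive
#'   for ascent). Zero rows for a flat series.
#' @export
detect_floor_changes <- function(pressure, fs, threshold = 40, window = 15,
                                 smooth_window = 4, atm = NULL) {
  assert_scalar_num(threshold, "threshold", positive = TRUE)
  assert_scalar_num(window, "window", positive = TRUE)
  n <- length(pressure)
  half <- round(window * fs / 2)
  empty <- data.frame(time = numeric(0), dp = numeric(0),
                      dheight = numeric(0))
  class(empty) <- c("floor_events", "data.frame")
  if (n < 2 * half + 1 || n < round(smooth_window * fs)) return(empty)
  B <- moving_mean(pressure, smooth_window, fs)
  centers <- (half + 1L):(n - half)
  d <- B[centers + half] - B[centers - half]
  hit <- abs(d) >= threshold
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  base_T <- if (is.null(atm)) 288.15 else atm$reference_temperature
  base_R <- if (is.null(atm)) 287.05 else atm$gas_constant_dry_air
  base_g <- if (is.null(atm)) 9.80665 else atm$gravity
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    j <- seg[which.max(abs(d[seg]))]
    ci <- centers[j]
    p_before <- B[ci - half]
    p_after <- B[ci + half]
    ref <- atmosphere_model(reference_pressure = p_before,
                            reference_temperature = base_T,
                            gas_constant_dry_air = base_R,
                            gravity = base_g)
    out[[length(out) + 1L]] <- data.frame(
      time = (ci - 1L) / fs,
      dp = p_after - p_before,
      dheight = pressure_to_height(p_after, ref))
  }
  res <- do.call(rbind, out)
  class(res) <- c("floor_events", "data.frame")
  res
}
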