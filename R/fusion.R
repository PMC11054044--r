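#' Fusion configuration
#'
#' Parameters of the temperature/pressure source-selection rule. Temperature
#' is the preferred respiration source while its running average is steady;
#' when the temperature average drifts by more than `temp_drift_threshold`
#' (default 0.1 degC/min) the pressure channel takes over, being insensitive
#' to ambient temperature up to the +/-1.3 Pa/K coefficient, which is far
#' below breath amplitude. When the pressure baseline is also unstable
#' (story transitions are ~50 Pa per ~10 s) the system pauses and reports no
#' rate.
#'
#' @param temp_drift_threshold Temperature drift threshold (degC/min).
#' @param drift_window Window over which drifts are measured (s).
#' @param pressure_baseline_threshold Pressure baseline-drift threshold
#'   (Pa per 10 s). The default 30 sits between breath-band dynamics and the
#'   ~50 Pa/10 s one-story signature.
#' @param evaluation_window Length of each rate-evaluation window (s).
#' @param evaluation_stride Stride between consecutive evaluations (s).
#' @param smooth_window Moving-mean window used to remove the breath band
#'   before measuring baseline drifts (s).
#' @param hysteresis Number of consecutive evaluations a new state must
#'   persist before the active source switches (chatter suppression).
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(temp_drift_threshold = 0.1,
                          drift_window = 60,
                          pressure_baseline_threshold = 30,
                          evaluation_window = 60,
                          evaluation_stride = 30,
                          smooth_window = 5,
                          hysteresis = 2) {
  assert_scalar_num(temp_drift_threshold, "temp_drift_threshold",
                    positive = TRUE)
  assert_scalar_num(drift_window, "drift_window", positive = TRUE)
  assert_scalar_num(pressure_baseline_threshold,
                    "pressure_baseline_threshold", positive = TRUE)
  assert_scalar_num(evaluation_window, "evaluation_window", positive = TRUE)
  assert_scalar_num(evaluation_stride, "evaluation_stride", positive = TRUE)
  assert_scalar_num(smooth_window, "smooth_window", positive = TRUE)
  assert_scalar_num(hysteresis, "hysteresis", positive = TRUE)
  structure(list(temp_drift_threshold = temp_drift_threshold,
                 drift_window = drift_window,
                 pressure_baseline_threshold = pressure_baseline_threshold,
                 evaluation_window = evaluation_window,
                 evaluation_stride = evaluation_stride,
                 smooth_window = smooth_window,
                 hysteresis = hysteresis),
            class = "fusion_config")
}

#' Baseline drift rate of a channel
#'
#' Slope of the moving mean of the series over the trailing `window` seconds,
#' expressed per minute. The moving mean removes the breath band; its
#' shrinking-window edges are trimmed before the least-squares fit so a pure
#' linear ramp yields its exact slope. Sign is preserved; threshold
#' comparisons use the absolute value.
#'
#' @param x Uniformly sampled series.
#' @param fs Sampling rate (Hz).
#' @param window Drift window (s); must not exceed the series duration.
#' @param smooth_window Moving-mean window (s) used before the fit.
#' @return Drift in channel units per minute.
#' @export
#' @examples
#' fs <- 10; t <- seq(0, 60 - 1 / fs, by = 1 / fs)
#' drift_rate(0.2 / 60 * t, fs)  # 0.2 per minute
drift_rate <- function(x, fs, window = 60, smooth_window = 5) {
  n <- length(x)
  if (window * fs > n) {
    stop("`window` is longer than the series", call. = FALSE)
  }
  nw <- round(window * fs)
  xs <- x[(n - nw + 1L):n]
  mm <- moving_mean(xs, smooth_window, fs)
  h <- ceiling(round(smooth_window * fs) / 2)
  keep <- (h + 1L):(nw - h)
  if (length(keep) < 2L) {
    stop("`window` too short relative to `smooth_window`", call. = FALSE)
  }
  tt <- (keep - 1L) / fs
  slope <- stats::cov(tt, mm[keep]) / stats::var(tt)
  60 * slope
}

#' Select the active respiration source
#'
#' Pure decision rule: temperature while its average is steady; pressure when
#' the temperature average drifts beyond threshold; paused when both the
#' temperature and the pressure baselines are unstable, in which case the
#' system waits for a state where processing can restart.
#'
#' @param temp_drift Temperature drift (degC/min, signed).
#' @param pressure_drift Pressure baseline drift (Pa per 10 s, signed).
#' @param cfg A [fusion_config()].
#' @return `"TEMPERATURE"`, `"PRESSURE"` or `"PAUSED"`.
#' @export
#' @examples
#' select_source(0.05, 5)   # TEMPERATURE
#' select_source(0.5, 5)    # PRESSURE
#' select_source(0.5, 60)   # PAUSED
select_source <- function(temp_drift, pressure_drift,
                          cfg = fusion_config()) {
  if (!is.finite(temp_drift) || !is.finite(pressure_drift)) {
    stop("drifts must be finite", call. = FALSE)
  }
  if (abs(temp_drift) <= cfg$temp_drift_threshold) {
    "TEMPERATURE"
  } else if (abs(pressure_drift) <= cfg$pressure_baseline_threshold) {
    "PRESSURE"
  } else {
    "PAUSED"
  }
}

#' Fused respiration estimate over a session
#'
#' Partitions the record into evaluation windows; in each window measures the
#' inner-temperature drift (degC/min) and the inner-pressure baseline drift
#' (Pa per 10 s, on the breath-band-removed moving mean), selects the active
#' source with [select_source()] (with hysteresis: the active source switches
#' only after the raw decision persists for `cfg$hysteresis` consecutive
#' evaluations), and computes the respiration rate on the selected inner
#' channel with [detect_breaths()]. Paused windows yield no rate and carry a
#' waiting flag.
#'
#' @param record A `dual_channel_record`.
#' @param cfg A [fusion_config()].
#' @param detector_cfg A [detector_config()]; its `min_amplitude` is applied
#'   to the pressure channel, and scaled by the resolution ratio for the
#'   temperature channel when left at the channel-agnostic default of 0
#'   (4x each channel's resolution is then used).
#' @return A data frame of class `fused_respiration` with one row per
#'   evaluation window: `t_start`, `t_end`, `temp_drift`, `pressure_drift`,
#'   `raw_source`, `source`, `rate`, `n_events`, `waiting`.
#' @export
fused_respiration <- function(record, cfg = fusion_config(),
                              detector_cfg = detector_config()) {
  if (!inherits(record, "dual_channel_record")) {
    stop("`record` must be a dual_channel_record", call. = FALSE)
  }
  fs <- record$sample_rate
  n <- length(record$time)
  total <- n / fs
  if (total < cfg$evaluation_window) {
    stop("record shorter than one evaluation window", call. = FALSE)
  }
  spec <- record$meta$spec %||% sensor_spec()
  amp_temp <- if (detector_cfg$min_amplitude > 0) detector_cfg$min_amplitude
              else 4 * spec$temp_resolution
  amp_press <- if (detector_cfg$min_amplitude > 0) detector_cfg$min_amplitude
               else 4 * spec$pressure_resolution

  starts <- seq(0, total - cfg$evaluation_window,
                by = cfg$evaluation_stride)
  k <- length(starts)
  out <- data.frame(t_start = starts,
                    t_end = starts + cfg$evaluation_window,
                    temp_drift = NA_real_, pressure_drift = NA_real_,
                    raw_source = NA_character_, source = NA_character_,
                    rate = NA_real_, n_events = NA_integer_,
                    waiting = FALSE)
  dwin <- min(cfg$drift_window, cfg$evaluation_window)
  current <- NULL
  streak <- 0L
  prev_raw <- NULL
  for (w in seq_len(k)) {
    i0 <- floor(starts[w] * fs) + 1L
    i1 <- min(n, i0 + round(cfg$evaluation_window * fs) - 1L)
    temp <- record$inner$temperature[i0:i1]
    press <- record$inner$pressure[i0:i1]
    td <- drift_rate(temp, fs, dwin, cfg$smooth_window)
    pd <- drift_rate(press, fs, dwin, cfg$smooth_window) / 6  # per 10 s
    raw <- select_source(td, pd, cfg)
    if (is.null(current)) {
      current <- raw
      streak <- 1L
    } else if (identical(raw, prev_raw) && !identical(raw, current)) {
      streak <- streak + 1L
      if (streak >= cfg$hysteresis) current <- raw
    } else if (!identical(raw, current)) {
      streak <- 1L
    }
    prev_raw <- raw
    out$temp_drift[w] <- td
    out$pressure_drift[w] <- pd
    out$raw_source[w] <- raw
    out$source[w] <- current
    if (current == "PAUSED") {
      out$waiting[w] <- TRUE
    } else {
      ch <- if (current == "TEMPERATURE") temp else press
      dcfg <- detector_cfg
      dcfg$min_amplitude <- if (current == "TEMPERATURE") amp_temp
                            else amp_press
      det <- detect_breaths(ch, fs, dcfg,
                            source = if (current == "TEMPERATURE")
                              "inner_temp" else "inner_pressure")
      out$rate[w] <- det$rate
      out$n_events[w] <- length(det$event_times)
    }
  }
  class(out) <- c("fused_respiration", "data.frame")
  out
}
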