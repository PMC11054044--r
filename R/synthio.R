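#' Simulator control parameters
#'
#' Tuning knobs of the session simulator that are properties of the device and
#' its environment rather than of the breathing pattern or the scenario.
#' Defaults emulate the reported behaviour of the mask-embedded node: inner
#' humidity saturating in 20-30 min (exponential approach, 550 s time
#' constant, 40 %rh start), AQI calibration status reaching "calibration in
#' progress" only after ~31 min and "calibrated" after 36 min, gas-resistance
#' breath oscillations of ~10 kOhm (outer) and ~3 kOhm (inner) peak-to-peak,
#' and per-floor barometric drops of 57.5 Pa ramped over ~10 s per flight.
#'
#' @param humidity_tau Humidity saturation time constant (s).
#' @param humidity_start Inner humidity at session start (%rh).
#' @param humidity_max Inner humidity asymptote (%rh), at most 100.
#' @param ambient_rh Ambient relative humidity (%rh).
#' @param outer_rh_attenuation Multiplicative bias of the outer humidity
#'   reading relative to ambient (the mask fabric captures humidity; outer
#'   readings of 30-40 %rh were reported under 80-100 %rh ambient).
#' @param inner_temp_offset Inner-minus-outer settled temperature (degC).
#' @param temp_tau_inner,temp_tau_outer First-order settling time constants of
#'   the two temperature channels toward the scripted segment temperature (s).
#' @param aqi_tau AQI settling time constant toward the segment level (s).
#' @param aqi_walk_sd,aqi_walk_ar Innovation sd and AR(1) coefficient of the
#'   bounded random walk superposed on the AQI level.
#' @param accuracy_times Times (s) at which the AQI accuracy status steps
#'   0 to 1, 1 to 2 and 2 to 3. The default reaches status 2 after 31 min, so
#'   reliable AQI requires more than half an hour of wear.
#' @param stair_ramp Duration of the pressure ramp of one flight of stairs (s).
#' @param stair_pause Landing pause between consecutive flights (s).
#' @param per_floor_drop Barometric drop per floor (Pa); 57.5 Pa is the centre
#'   of the reported 55-60 Pa band and corresponds to a ~4.7 m story.
#' @param temp_noise_sd,pressure_noise_sd,humidity_noise_sd Per-sample
#'   Gaussian RMS noise of each channel (degC, Pa, %rh), truncated at the
#'   channel's accuracy bound. Defaults are realistic high-rate RMS noise
#'   figures for this sensor class (noise well below the accuracy bounds,
#'   which are dominated by bias).
#' @param bias Draw one constant per-session offset per channel and side,
#'   uniform within half the accuracy bound? Accuracy budgets of this sensor
#'   class are dominated by slowly varying bias, not white noise.
#' @param gas_outer_base,gas_inner_base Gas-resistance baselines (Ohm).
#' @param gas_outer_p2p,gas_inner_p2p Gas-resistance breath peak-to-peak (Ohm).
#' @param gas_noise_sd Gas-resistance noise sd (Ohm).
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(humidity_tau = 550,
                        humidity_start = 40,
                        humidity_max = 99,
                        ambient_rh = 90,
                        outer_rh_attenuation = 0.4,
                        inner_temp_offset = 1,
                        temp_tau_inner = 40,
                        temp_tau_outer = 20,
                        aqi_tau = 60,
                        aqi_walk_sd = 0.2,
                        aqi_walk_ar = 0.999,
                        accuracy_times = c(300, 1860, 2160),
                        stair_ramp = 10,
                        stair_pause = 12,
                        per_floor_drop = 57.5,
                        temp_noise_sd = 0.01,
                        pressure_noise_sd = 1.2,
                        humidity_noise_sd = 0.1,
                        bias = TRUE,
                        gas_outer_base = 1e5,
                        gas_inner_base = 5e4,
                        gas_outer_p2p = 1e4,
                        gas_inner_p2p = 3e3,
                        gas_noise_sd = 200) {
  assert_scalar_num(humidity_tau, "humidity_tau", positive = TRUE)
  assert_scalar_num(humidity_max, "humidity_max", lower = 0, upper = 100)
  assert_scalar_num(humidity_start, "humidity_start", lower = 0, upper = 100)
  assert_scalar_num(temp_noise_sd, "temp_noise_sd", nonneg = TRUE)
  assert_scalar_num(pressure_noise_sd, "pressure_noise_sd", nonneg = TRUE)
  assert_scalar_num(humidity_noise_sd, "humidity_noise_sd", nonneg = TRUE)
  assert_scalar_num(per_floor_drop, "per_floor_drop", positive = TRUE)
  if (length(accuracy_times) != 3L || is.unsorted(accuracy_times)) {
    stop("`accuracy_times` must be three non-decreasing times", call. = FALSE)
  }
  structure(list(humidity_tau = humidity_tau,
                 humidity_start = humidity_start,
                 humidity_max = humidity_max,
                 ambient_rh = ambient_rh,
                 outer_rh_attenuation = outer_rh_attenuation,
                 inner_temp_offset = inner_temp_offset,
                 temp_tau_inner = temp_tau_inner,
                 temp_tau_outer = temp_tau_outer,
                 aqi_tau = aqi_tau,
                 aqi_walk_sd = aqi_walk_sd,
                 aqi_walk_ar = aqi_walk_ar,
                 accuracy_times = accuracy_times,
                 stair_ramp = stair_ramp,
                 stair_pause = stair_pause,
                 per_floor_drop = per_floor_drop,
                 temp_noise_sd = temp_noise_sd,
                 pressure_noise_sd = pressure_noise_sd,
                 humidity_noise_sd = humidity_noise_sd,
                 bias = bias,
                 gas_outer_base = gas_outer_base,
                 gas_inner_base = gas_inner_base,
                 gas_outer_p2p = gas_outer_p2p,
                 gas_inner_p2p = gas_inner_p2p,
                 gas_noise_sd = gas_noise_sd),
            class = "sim_control")
}

#' Inner-humidity saturation profile
#'
#' Exponential approach of the in-mask humidity toward its asymptote,
#' emulating the saturation of the inner humidity channel after 20-30 minutes
#' of wear. With the defaults the profile crosses 95 %rh at ~22 minutes.
#'
#' @param t Time since session start (s); vectorized, must be non-negative.
#' @param time_constant Time constant of the exponential approach (s).
#' @param start Humidity at `t = 0` (%rh).
#' @param max Asymptote (%rh), at most 100.
#' @return Humidity (%rh), monotone non-decreasing in `t`, bounded by `max`.
#' @export
#' @examples
#' saturation_profile(c(0, 600, 1500, 1800))
saturation_profile <- function(t, time_constant = 500, start = 40, max = 99) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be non-negative", call. = FALSE)
  }
  assert_scalar_num(time_constant, "time_constant", positive = TRUE)
  assert_scalar_num(start, "start", lower = 0, upper = 100)
  assert_scalar_num(max, "max", lower = 0, upper = 100)
  start + (max - start) * (1 - exp(-t / time_constant))
}

## breath waveform, one cycle per unit phase; rising mean-crossing once per
## cycle for both shapes
breath_waveform <- function(phase, waveform) {
  switch(waveform,
         sinusoid = sin(2 * pi * phase),
         asymmetric = sin(2 * pi * phase + 0.5 * sin(2 * pi * phase)),
         stop("unknown waveform: ", waveform, call. = FALSE))
}

## per-segment pressure baseline, including stair ramps; returns the baseline
## vector and the scripted floor-event truth table
pressure_baseline_profile <- function(segments, t, control) {
  n <- length(t)
  pb <- numeric(n)
  cur <- if (!is.na(segments$pressure_baseline[1])) {
    segments$pressure_baseline[1]
  } else {
    101325
  }
  truth <- list()
  for (k in seq_len(nrow(segments))) {
    idx <- which(t >= segments$t_start[k] & t < segments$t_end[k])
    base <- if (!is.na(segments$pressure_baseline[k])) {
      segments$pressure_baseline[k]
    } else {
      cur
    }
    fd <- segments$floor_delta[k]
    if (fd == 0) {
      pb[idx] <- base
      cur <- base
    } else {
      nf <- abs(fd)
      ramp <- control$stair_ramp
      pause <- control$stair_pause
      need <- nf * ramp + (nf - 1) * pause
      if (segments$duration[k] < need) {
        stop(sprintf(paste0("stairs segment %d too short: %d floor(s) need ",
                            ">= %.0f s (%.0f s ramp + %.0f s landing pause)"),
                     k, nf, need, ramp, pause), call. = FALSE)
      }
      tl <- t[idx] - segments$t_start[k]
      drop <- sign(fd) * control$per_floor_drop
      prof <- numeric(length(idx))
      for (f in seq_len(nf)) {
        r0 <- (f - 1) * (ramp + pause)
        prof <- prof - drop * pmin(pmax((tl - r0) / ramp, 0), 1)
        p_before <- base - (f - 1) * drop
        p_after <- base - f * drop
        truth[[length(truth) + 1L]] <-
          data.frame(time = segments$t_start[k] + r0 + ramp / 2,
                     dp = -drop,
                     dheight = pressure_to_height(
                       p_after,
                       atmosphere_model(reference_pressure = p_before)))
      }
      pb[idx] <- base + prof
      cur <- base - fd * control$per_floor_drop
    }
  }
  list(baseline = pb,
       floor_truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Simulate a dual-channel sensor session
#'
#' Produces a synchronized inner+outer sensor record (temperature, pressure,
#' humidity, gas resistance; AQI and AQI accuracy status on the outer side
#' only) for a scripted scenario. The record carries the generator truth in
#' its metadata so downstream detectors can be validated against it.
#'
#' Signal construction per sample: segment temperatures are approached with
#' first-order settling; the inner pressure carries the breath oscillation at
#' full amplitude while the outer channel sees it attenuated; the temperature
#' oscillation is the stutter-free fundamental of the breath drive evaluated
#' `temp_lag` seconds in the past (thermal inertia smooths stutters away and
#' delays the response); stairs segments ramp the barometric baseline by one
#' per-floor drop per ~10 s flight with a landing pause between flights;
#' inner humidity follows [saturation_profile()]; AQI relaxes toward the
#' scripted segment level with a bounded random walk on top and its accuracy
#' status steps 0-1-2-3 at the configured settling times. All channels receive
#' truncated Gaussian noise plus an optional constant per-session bias within
#' the accuracy bound, and are quantized to the sensor resolutions.
#'
#' @param script A [scenario_script()].
#' @param breathing A [breathing_model()].
#' @param spec A [sensor_spec()].
#' @param seed Integer seed; identical inputs yield bit-identical records.
#' @param sample_rate Sampling rate (Hz), default 10.
#' @param control A [sim_control()].
#' @return An object of class `dual_channel_record`: a list with elements
#'   `sample_rate`, `time`, `inner` (data frame: `temperature`, `pressure`,
#'   `humidity`, `gas`), `outer` (additionally `aqi`, `aqi_accuracy`) and
#'   `meta` (seed, script, breathing model, spec, control, stutter and floor
#'   truth).
#' @export
#' @examples
#' rec <- simulate_session(flat_scenario(60), seed = 1)
#' str(rec$inner)
simulate_session <- function(script,
                             breathing = breathing_model(),
                             spec = sensor_spec(),
                             seed,
                             sample_rate = 10,
                             control = sim_control()) {
  if (!inherits(script, "scenario_script")) {
    stop("`script` must be a scenario_script", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required for reproducibility",
                          call. = FALSE)
  assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  segments <- script$segments
  dt <- 1 / sample_rate
  total <- sum(segments$duration)
  n <- floor(total * sample_rate)
  t <- (seq_len(n) - 1) * dt

  with_seed(seed, {
    seg_id <- findInterval(t, segments$t_start)
    target_temp <- segments$ambient_temp[seg_id]

    outer_temp_base <- relax_toward(target_temp, control$temp_tau_outer, dt)
    inner_temp_base <- relax_toward(target_temp + control$inner_temp_offset,
                                    control$temp_tau_inner, dt)

    bp <- pressure_baseline_profile(segments, t, control)

    ## breath drive: phase in cycles; a stutter adds a second harmonic that
    ## splits the pressure peak (one extra rising mean-crossing per stutter)
    phase0 <- stats::runif(1)
    phase <- breathing$rate / 60 * t + phase0
    cyc <- floor(phase)
    n_cyc <- max(cyc) + 1L
    stutter_cycle <- stats::runif(n_cyc) < breathing$stutter_prob
    stutter <- stutter_cycle[cyc + 1L]
    press_wave <- breath_waveform(phase, breathing$waveform) +
      ifelse(stutter, 0.8 * sin(4 * pi * phase), 0)
    phase_lag <- breathing$rate / 60 * (t - breathing$temp_lag) + phase0
    temp_wave <- sin(2 * pi * phase_lag)  # thermal inertia keeps fundamental
    atten <- breathing$outer_pressure_p2p / breathing$inner_pressure_p2p

    inner_press <- bp$baseline + breathing$inner_pressure_p2p / 2 * press_wave
    outer_press <- bp$baseline + breathing$outer_pressure_p2p / 2 * press_wave
    inner_temp <- inner_temp_base + breathing$inner_temp_p2p / 2 * temp_wave
    outer_temp <- outer_temp_base +
      breathing$inner_temp_p2p / 2 * atten * temp_wave

    inner_hum <- saturation_profile(t, control$humidity_tau,
                                    control$humidity_start,
                                    control$humidity_max)
    outer_hum <- rep(control$ambient_rh * control$outer_rh_attenuation, n)

    gas_wave <- sin(2 * pi * phase)
    inner_gas <- control$gas_inner_base + control$gas_inner_p2p / 2 * gas_wave
    outer_gas <- control$gas_outer_base + control$gas_outer_p2p / 2 * gas_wave

    ## AQI (outer only): relax toward segment level + bounded AR(1) walk
    aqi_level <- relax_toward(segments$ambient_aqi[seg_id], control$aqi_tau,
                              dt)
    walk <- as.numeric(stats::filter(stats::rnorm(n, 0, control$aqi_walk_sd),
                                     control$aqi_walk_ar,
                                     method = "recursive"))
    aqi <- pmin(pmax(aqi_level + walk, 0), 500)
    acc_t <- control$accuracy_times
    aqi_accuracy <- findInterval(t, acc_t)  # 0,1,2,3

    noisy_quant <- function(x, sd, bound, res, lo = -Inf, hi = Inf) {
      b <- if (isTRUE(control$bias)) stats::runif(1, -bound / 2, bound / 2)
           else 0
      pmin(pmax(quantize(x + b + rnorm_trunc(n, sd, bound), res), lo), hi)
    }

    inner <- data.frame(
      temperature = noisy_quant(inner_temp, control$temp_noise_sd,
                                spec$temp_abs_accuracy,
                                spec$temp_resolution),
      pressure = noisy_quant(inner_press, control$pressure_noise_sd,
                             spec$pressure_rel_accuracy,
                             spec$pressure_resolution),
      humidity = noisy_quant(inner_hum, control$humidity_noise_sd,
                             spec$humidity_abs_accuracy,
                             spec$humidity_resolution, 0, 100),
      gas = round(inner_gas + stats::rnorm(n, 0, control$gas_noise_sd))
    )
    outer <- data.frame(
      temperature = noisy_quant(outer_temp, control$temp_noise_sd,
                                spec$temp_abs_accuracy,
                                spec$temp_resolution),
      pressure = noisy_quant(outer_press, control$pressure_noise_sd,
                             spec$pressure_rel_accuracy,
                             spec$pressure_resolution),
      humidity = noisy_quant(outer_hum, control$humidity_noise_sd,
                             spec$humidity_abs_accuracy,
                             spec$humidity_resolution, 0, 100),
      gas = round(outer_gas + stats::rnorm(n, 0, control$gas_noise_sd)),
      aqi = round(aqi, 1),
      aqi_accuracy = as.integer(aqi_accuracy)
    )

    rng <- range(c(inner$pressure, outer$pressure))
    if (rng[1] < 30000 || rng[2] > 110000) {
      stop("simulated pressure left the 300-1100 hPa sensor range",
           call. = FALSE)
    }

    structure(list(sample_rate = sample_rate,
                   time = t,
                   inner = inner,
                   outer = outer,
                   meta = list(seed = seed,
                               scenario = script$name,
                               script = script,
                               breathing = breathing,
                               spec = spec,
                               control = control,
                               n_stutters = sum(stutter_cycle[unique(cyc) +
                                                                1L]),
                               stutter_cycles = which(stutter_cycle) - 1L,
                               floor_truth = bp$floor_truth,
                               gaps = NULL)),
              class = "dual_channel_record")
  })
}

#' @export
print.dual_channel_record <- function(x, ...) {
  cat(sprintf(paste0("<dual_channel_record: %d samples/side at %g Hz ",
                     "(%.1f min), scenario '%s', seed %s>\n"),
              length(x$time), x$sample_rate,
              length(x$time) / x$sample_rate / 60,
              x$meta$scenario %||% "?", format(x$meta$seed %||% NA)))
  invisible(x)
}
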