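#' Run the full analysis pipeline
#'
#' Wires all stages end to end: simulate (or load) a session, compute the
#' fused respiration trace, detect floor transitions on the outer pressure,
#' segment the session into urban zones, assess AQI reliability and
#' inner-humidity validity, evaluate the power budget, and, when particle
#' count sets are supplied, the filtration-efficiency table. The run is
#' deterministic given the seed; stages remain runnable independently through
#' their own functions with files as the only interface.
#'
#' @param config Named list. Recognized keys (unknown keys are rejected):
#'   \describe{
#'     \item{seed}{integer seed (required unless `session` is given)}
#'     \item{scenario}{a [scenario_script()]; default [demo_scenario()]}
#'     \item{session}{path to a session CSV, or a `dual_channel_record`;
#'       overrides simulation}
#'     \item{breathing, spec, control, sample_rate}{simulator settings}
#'     \item{detector, fusion, zones}{stage configurations}
#'     \item{altimetry}{list of overrides for [detect_floor_changes()]
#'       (`threshold`, `window`)}
#'     \item{capacity}{battery capacity (mAh), default 180}
#'     \item{power_entries}{budget table, default [default_power_budget()]}
#'     \item{ambient_particles, behind_particles}{[particle_counts()] pair
#'       for the optional filtration section}
#'   }
#' @return An object of class `pipeline_report`: list with sections
#'   `respiration` (fused trace), `floors`, `zones`, `aqi` (gating +
#'   humidity validity), `power`, optionally `pfe`, and `config_echo`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(seed = 1, scenario = flat_scenario(180)))
#' rep$respiration
#' }
run_pipeline <- function(config = list()) {
  allowed <- c("seed", "scenario", "session", "breathing", "spec", "control",
               "sample_rate", "detector", "fusion", "zones", "altimetry",
               "capacity", "power_entries", "ambient_particles",
               "behind_particles")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  record <- if (!is.null(config$session)) {
    if (inherits(config$session, "dual_channel_record")) config$session
    else read_session(config$session)
  } else {
    if (is.null(config$seed)) {
      stop("config must provide `seed` (or a `session`)", call. = FALSE)
    }
    simulate_session(config$scenario %||% demo_scenario(),
                     breathing = config$breathing %||% breathing_model(),
                     spec = config$spec %||% sensor_spec(),
                     seed = config$seed,
                     sample_rate = config$sample_rate %||% 10,
                     control = config$control %||% sim_control())
  }
  fs <- record$sample_rate
  fused <- fused_respiration(record,
                             cfg = config$fusion %||% fusion_config(),
                             detector_cfg = config$detector %||%
                               detector_config())
  alt <- config$altimetry %||% list()
  floors <- detect_floor_changes(record$outer$pressure, fs,
                                 threshold = alt$threshold %||% 40,
                                 window = alt$window %||% 15)
  zones <- segment_zones(record$outer$temperature, fs,
                         aqi = aqi_samples(record),
                         cfg = config$zones %||% zone_config())
  gating <- gate_by_accuracy(aqi_samples(record))
  humidity <- humidity_validity(record$inner$humidity, fs)
  power <- power_budget(config$power_entries %||% default_power_budget(),
                        capacity = config$capacity %||% 180)
  report <- list(
    respiration = fused,
    floors = floors,
    zones = zones,
    aqi = list(time_to_reliability = gating$time_to_reliability,
               n_reliable = sum(gating$samples$reliable),
               humidity = humidity),
    power = power,
    config_echo = list(seed = record$meta$seed,
                       scenario = record$meta$scenario,
                       sample_rate = fs,
                       n_samples = length(record$time))
  )
  if (!is.null(config$ambient_particles) &&
      !is.null(config$behind_particles)) {
    report$pfe <- pfe(config$ambient_particles, config$behind_particles)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== maskmonitor pipeline report ==\n")
  cat(sprintf("session: scenario '%s', seed %s, %d samples at %g Hz\n",
              x$config_echo$scenario, format(x$config_echo$seed),
              x$config_echo$n_samples, x$config_echo$sample_rate))
  act <- x$respiration$rate[!x$respiration$waiting]
  cat(sprintf("respiration: %d evaluation windows, median rate %.1f /min",
              nrow(x$respiration), stats::median(act, na.rm = TRUE)),
      sprintf("(%d paused)\n", sum(x$respiration$waiting)))
  cat(sprintf("floors: %d transition(s)", nrow(x$floors)))
  if (nrow(x$floors)) {
    cat(sprintf(", total height change %+.1f m", sum(x$floors$dheight)))
  }
  cat("\n")
  cat(sprintf("zones: %d segment(s): %s\n", nrow(x$zones),
              paste(x$zones$label, collapse = " > ")))
  cat(sprintf("aqi: reliable after %.1f min; inner humidity %s\n",
              x$aqi$time_to_reliability / 60,
              if (x$aqi$humidity$invalid)
                sprintf("invalid from %.1f min",
                        x$aqi$humidity$invalid_from / 60)
              else "valid throughout"))
  cat(sprintf("power: %.4f mA average -> %.1f h on %g mAh\n",
              x$power$average_current, x$power$endurance,
              x$power$capacity))
  if (!is.null(x$pfe)) {
    cat(sprintf("pfe: %d bins, mean efficiency %.1f%%\n", nrow(x$pfe),
                mean(x$pfe$pfe[is.finite(x$pfe$pfe)])))
  }
  invisible(x)
}
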