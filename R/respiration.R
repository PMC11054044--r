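#' Centered moving mean with shrinking edges
#'
#' The running average used as the crossing threshold by the breath detector.
#' The window is centered on each sample and shrinks near the edges, so the
#' output has the same length as the input and a constant series maps to
#' itself.
#'
#' @param x Uniformly sampled numeric series.
#' @param window Window length in seconds (or in samples when `fs = 1`).
#' @param fs Sampling rate (Hz); the window spans `round(window * fs)`
#'   samples, which must be at least 2 and at most `length(x)`.
#' @return Numeric series of the same length as `x`.
#' @export
#' @examples
#' moving_mean(c(0, 1, 2, 3, 4), 3)  # 0.5 1 2 3 3.5
moving_mean <- function(x, window, fs = 1) {
  n <- length(x)
  nw <- round(window * fs)
  if (nw < 2) stop("`window` must span at least 2 samples", call. = FALSE)
  if (nw > n) stop("`window` is longer than the series", call. = FALSE)
  hl <- (nw - 1L) %/% 2L
  hr <- nw %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - hl)
  hi <- pmin(n, i + hr)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Breath detector configuration
#'
#' @param window Moving-mean window (s). The default 5 s is about one breath
#'   period at 12 breaths/min, so the mean tracks the baseline but not
#'   individual breaths.
#' @param min_breath_interval Refractory period between events (s); the
#'   default 1.5 s caps the detectable rate at 40 breaths/min, above the
#'   normal 12-20 range.
#' @param min_amplitude Minimum local peak-to-peak (channel units) for an
#'   event to count; suppresses quantization chatter. A sensible default is
#'   4x the channel resolution.
#' @param crossing_edge Count `"rising"` (default) or `"falling"` crossings of
#'   the moving mean; one full rise-fall pair is one breath.
#' @param debounce Minimum time (s) the series must persist on one side of
#'   the moving mean for the side change to count as a crossing. Suppresses
#'   noise chatter around the threshold without any signal pre-filtering;
#'   0 disables it. The default 0.3 s is well below the above-mean phase of a
#'   breath even at 40 breaths/min.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(window = 5,
                            min_breath_interval = 1.5,
                            min_amplitude = 0,
                            crossing_edge = c("rising", "falling"),
                            debounce = 0.3) {
  crossing_edge <- match.arg(crossing_edge)
  assert_scalar_num(window, "window", positive = TRUE)
  assert_scalar_num(min_breath_interval, "min_breath_interval",
                    positive = TRUE)
  assert_scalar_num(min_amplitude, "min_amplitude", nonneg = TRUE)
  assert_scalar_num(debounce, "debounce", nonneg = TRUE)
  structure(list(window = window,
                 min_breath_interval = min_breath_interval,
                 min_amplitude = min_amplitude,
                 crossing_edge = crossing_edge,
                 debounce = debounce),
            class = "detector_config")
}

#' Detect breaths by moving-mean threshold crossing
#'
#' Counts breaths as crossings of the series through its own moving mean, in
#' the configured edge direction, with no pre-filtering (at 10 Hz sampling no
#' low-pass is needed). A candidate crossing is kept if it occurs at least
#' `min_breath_interval` after the previous kept event and the local
#' peak-to-peak since the previous event reaches `min_amplitude`.
#'
#' @param x Uniformly sampled numeric series (one channel).
#' @param fs Sampling rate (Hz).
#' @param cfg A [detector_config()].
#' @param source Optional label of the source channel (e.g.
#'   `"inner_pressure"`), stored in the result.
#' @return An object of class `breath_detection`: list with `event_times`
#'   (s), `rate` (breaths/min, `60 * count / duration`), `per_breath_p2p`
#'   (channel units, from [peak_to_peak_stats()]), `duration` (s) and
#'   `source`. A constant series yields zero events and rate 0.
#' @export
#' @examples
#' fs <- 10; t <- seq(0, 60 - 1 / fs, by = 1 / fs)
#' d <- detect_breaths(sin(2 * pi * 15 / 60 * t), fs)
#' d$rate  # 15
detect_breaths <- function(x, fs, cfg = detector_config(), source = NA) {
  n <- length(x)
  duration <- n / fs
  if (duration < 2 * cfg$window) {
    stop("series must span at least twice the moving-mean window",
         call. = FALSE)
  }
  mm <- moving_mean(x, cfg$window, fs)
  above <- x > mm
  ## debounced side-of-mean state: a side change registers only once the new
  ## side persists, so threshold chatter never splits or fabricates breaths
  nb <- max(1L, round(cfg$debounce * fs))
  r <- rle(above)
  run_start <- cumsum(r$lengths) - r$lengths + 1L
  state <- r$values[1]
  cand <- integer(0)
  want <- cfg$crossing_edge == "rising"
  for (k in seq_along(r$lengths)) {
    if (r$values[k] != state && r$lengths[k] >= nb) {
      state <- r$values[k]
      if (state == want) cand <- c(cand, run_start[k])
    }
  }
  events <- integer(0)
  last_t <- -Inf
  seg_start <- 1L
  for (i in cand) {
    ti <- (i - 1L) / fs
    if (ti - last_t < cfg$min_breath_interval) next
    p2p <- diff(range(x[seg_start:i]))
    if (p2p < cfg$min_amplitude) next
    events <- c(events, i)
    last_t <- ti
    seg_start <- i
  }
  event_times <- (events - 1L) / fs
  det <- structure(list(event_times = event_times,
                        rate = 60 * length(events) / duration,
                        per_breath_p2p = numeric(0),
                        duration = duration,
                        source = source),
                   class = "breath_detection")
  if (length(events) > 0) {
    det$per_breath_p2p <- peak_to_peak_stats(x, fs, det)$per_breath
  }
  det
}

#' @export
print.breath_detection <- function(x, ...) {
  cat(sprintf(paste0("<breath_detection: %d events in %.0f s, ",
                     "rate %.1f breaths/min%s>\n"),
              length(x$event_times), x$duration, x$rate,
              if (!is.na(x$source)) paste0(", source ", x$source) else ""))
  invisible(x)
}

#' Per-breath peak-to-peak amplitude summary
#'
#' Amplitude of each breath measured as max minus min of the channel between
#' consecutive detected events (for a pure sinusoid of amplitude A this is
#' ~2A per breath).
#'
#' @param x The channel the events were detected on.
#' @param fs Sampling rate (Hz).
#' @param detection A `breath_detection` (or anything with `$event_times`).
#' @return List with `per_breath` (vector of peak-to-peak amplitudes),
#'   `mean`, `min` and `max`; all empty/NA when fewer than one event.
#' @export
peak_to_peak_stats <- function(x, fs, detection) {
  ev <- round(detection$event_times * fs) + 1L
  if (length(ev) < 1L) {
    return(list(per_breath = numeric(0), mean = NA_real_, min = NA_real_,
                max = NA_real_))
  }
  bounds <- c(ev, length(x))
  p2p <- vapply(seq_len(length(bounds) - 1L), function(k) {
    seg <- x[bounds[k]:bounds[k + 1L]]
    diff(range(seg))
  }, numeric(1))
  p2p <- p2p[bounds[-length(bounds)] != bounds[-1L]]
  list(per_breath = p2p, mean = mean(p2p), min = min(p2p), max = max(p2p))
}
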