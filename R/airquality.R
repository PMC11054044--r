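#' AQI class table
#'
#' The seven AQI classes covering the 0-500 index range: 0-50 excellent,
#' 51-100 good, 101-150 lightly polluted, 151-200 moderately polluted,
#' 201-250 heavily polluted, 251-350 severely polluted, 351-500 extremely
#' polluted. Classes are contiguous and partition the range; class index is
#' monotone in the value.
#'
#' @return Data frame with `lower`, `upper` and `label`.
#' @export
aqi_classes <- function() {
  data.frame(lower = c(0, 51, 101, 151, 201, 251, 351),
             upper = c(50, 100, 150, 200, 250, 350, 500),
             label = c("excellent", "good", "lightly polluted",
                       "moderately polluted", "heavily polluted",
                       "severely polluted", "extremely polluted"))
}

#' Classify AQI values
#'
#' @param value AQI values in `[0, 500]`; vectorized. Non-integer values fall
#'   into the class whose upper printed bound they do not exceed.
#' @return Ordered factor of class labels.
#' @export
#' @examples
#' classify_aqi(c(25, 75, 400))
classify_aqi <- function(value) {
  if (any(!is.finite(value)) || any(value < 0 | value > 500)) {
    stop("AQI values must lie in [0, 500]", call. = FALSE)
  }
  cls <- aqi_classes()
  uppers <- cls$upper[-nrow(cls)]
  idx <- rowSums(outer(value, uppers, ">")) + 1L
  factor(cls$label[idx], levels = cls$label, ordered = TRUE)
}

#' Gate AQI samples by calibration status
#'
#' The sensor stack reports an accuracy status with each AQI value
#' (0 stabilization in progress, 1 calibration required, 2 calibration in
#' progress, 3 calibrated). Values before the status reaches `min_status`
#' are unreliable; the stack needs more than half an hour of varied exposure
#' to reach a calibrated state.
#'
#' @param samples Data frame with columns `time` (s), `value` (AQI) and
#'   `accuracy` (integer 0-3), e.g. built from the outer side of a
#'   `dual_channel_record`.
#' @param min_status Minimum accuracy status considered reliable (default 2).
#' @return An object of class `aqi_gating`: list with `samples` (input plus a
#'   logical `reliable` column), `time_to_reliability` (s, `Inf` if never
#'   reliable) and `min_status`.
#' @export
gate_by_accuracy <- function(samples, min_status = 2) {
  if (!all(c("time", "value", "accuracy") %in% names(samples))) {
    stop("`samples` needs columns time, value, accuracy", call. = FALSE)
  }
  if (!min_status %in% 0:3) {
    stop("`min_status` must be in 0..3", call. = FALSE)
  }
  if (any(!samples$accuracy %in% 0:3)) {
    stop("accuracy status must be in 0..3", call. = FALSE)
  }
  samples$reliable <- samples$accuracy >= min_status
  ttr <- if (any(samples$reliable)) min(samples$time[samples$reliable])
         else Inf
  structure(list(samples = samples, time_to_reliability = ttr,
                 min_status = min_status),
            class = "aqi_gating")
}

#' @export
print.aqi_gating <- function(x, ...) {
  cat(sprintf(paste0("<aqi_gating: %d/%d samples reliable (status >= %d), ",
                     "time to reliability %s>\n"),
              sum(x$samples$reliable), nrow(x$samples), x$min_status,
              if (is.finite(x$time_to_reliability))
                sprintf("%.0f s (%.1f min)", x$time_to_reliability,
                        x$time_to_reliability / 60)
              else "never"))
  invisible(x)
}

#' Humidity-channel validity
#'
#' The in-mask humidity channel saturates after 20-30 minutes of wear, after
#' which it carries no usable information. The channel is flagged invalid
#' from the first time humidity stays at or above `saturation_level` for
#' `sustain` seconds (a brief spike does not invalidate it).
#'
#' @param humidity Uniformly sampled humidity series (%rh).
#' @param fs Sampling rate (Hz).
#' @param saturation_level Saturation threshold (%rh), default 95.
#' @param sustain Required sustained duration (s), default 60.
#' @return List with `invalid` (logical), `invalid_from` (s, `NA` when the
#'   channel stays valid) and the parameters used.
#' @export
humidity_validity <- function(humidity, fs, saturation_level = 95,
                              sustain = 60) {
  if (length(humidity) == 0L) stop("empty humidity series", call. = FALSE)
  sat <- humidity >= saturation_level
  need <- max(1L, round(sustain * fs))
  r <- rle(sat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  invalid_from <- if (length(hit)) (starts[hit[1]] - 1L) / fs else NA_real_
  list(invalid = length(hit) > 0, invalid_from = invalid_from,
       saturation_level = saturation_level, sustain = sustain)
}

#' Zone segmentation configuration
#'
#' @param temp_step Outer-temperature baseline shift (degC) that opens a zone
#'   boundary.
#' @param aqi_step Reliable-AQI shift that opens a zone boundary.
#' @param window Span (s) of the centered baseline difference used for
#'   change-point detection.
#' @param smooth_window Moving-mean window (s) applied before differencing.
#' @param indoor_temp Mean outer temperature (degC) at or above which a
#'   segment is labeled indoor (in-mask readings reach almost 30 degC
#'   indoors).
#' @param outdoor_temp Mean outer temperature (degC) below which a segment is
#'   labeled outdoor (street readings settle near 22-23 degC).
#' @param transit_aqi Mean reliable AQI above which an intermediate-
#'   temperature segment is labeled transit.
#' @param min_status Minimum AQI accuracy status used as evidence.
#' @param min_gap Minimum spacing (s) between distinct boundaries.
#' @return A list of class `zone_config`.
#' @export
zone_config <- function(temp_step = 3, aqi_step = 50, window = 60,
                        smooth_window = 10, indoor_temp = 26,
                        outdoor_temp = 24, transit_aqi = 120,
                        min_status = 2, min_gap = 30) {
  assert_scalar_num(temp_step, "temp_step", positive = TRUE)
  assert_scalar_num(aqi_step, "aqi_step", positive = TRUE)
  assert_scalar_num(window, "window", positive = TRUE)
  structure(list(temp_step = temp_step, aqi_step = aqi_step,
                 window = window, smooth_window = smooth_window,
                 indoor_temp = indoor_temp, outdoor_temp = outdoor_temp,
                 transit_aqi = transit_aqi, min_status = min_status,
                 min_gap = min_gap),
            class = "zone_config")
}

## change-point times from a centered baseline difference; x may carry NAs
## (masked unreliable stretches), which never produce boundaries
baseline_changepoints <- function(x, fs, step, window, smooth_window) {
  n <- length(x)
  half <- round(window * fs / 2)
  if (n < 2 * half + 1 || n < round(smooth_window * fs)) return(numeric(0))
  filled <- x
  if (anyNA(filled)) {
    ok <- which(!is.na(filled))
    if (length(ok) < 2L) return(numeric(0))
    filled <- stats::approx(ok, filled[ok], xout = seq_len(n),
                            rule = 2)$y
  }
  B <- moving_mean(filled, smooth_window, fs)
  centers <- (half + 1L):(n - half)
  d <- B[centers + half] - B[centers - half]
  ## a difference that straddles masked samples is not evidence
  if (anyNA(x)) {
    bad <- is.na(x)
    cbad <- cumsum(bad)
    span_bad <- (cbad[centers + half] -
                   c(0, cbad)[centers - half + 1L]) > 0
    d[span_bad] <- 0
  }
  hit <- abs(d) >= step
  if (!any(hit)) return(numeric(0))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  times <- numeric(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    j <- seg[which.max(abs(d[seg]))]
    times <- c(times, (centers[j] - 1L) / fs)
  }
  times
}

#' Segment a session into urban zones
#'
#' Splits a session at change-points where the outer-temperature baseline
#' shifts by at least `temp_step` or the reliable AQI shifts by at least
#' `aqi_step`, then labels each segment: indoor when the mean outer
#' temperature reaches `indoor_temp`, outdoor when it is below
#' `outdoor_temp`, transit when the temperature is intermediate and the mean
#' reliable AQI is elevated, and unknown when the temperature is intermediate
#' and no reliable AQI is available. AQI samples recorded before the
#' calibration status reaches `min_status` never create boundaries.
#'
#' @param outer_temp Uniformly sampled outer-temperature series (degC).
#' @param fs Sampling rate (Hz).
#' @param aqi Optional data frame of AQI samples (`time`, `value`,
#'   `accuracy`) aligned to the same clock.
#' @param cfg A [zone_config()].
#' @return A data frame of class `zone_segments` with `start`, `end` (s),
#'   `label`, `mean_outer_temp` and `mean_aqi` (reliable samples only, `NA`
#'   when none). Segments tile the session without overlap.
#' @export
segment_zones <- function(outer_temp, fs, aqi = NULL, cfg = zone_config()) {
  n <- length(outer_temp)
  total <- n / fs
  bt <- baseline_changepoints(outer_temp, fs, cfg$temp_step, cfg$window,
                              cfg$smooth_window)
  ba <- numeric(0)
  rel <- NULL
  if (!is.null(aqi) && nrow(aqi) > 0) {
    gated <- gate_by_accuracy(aqi, cfg$min_status)
    rel <- gated$samples
    v <- rel$value
    v[!rel$reliable] <- NA_real_
    ba <- baseline_changepoints(v, fs, cfg$aqi_step, cfg$window,
                                cfg$smooth_window)
  }
  bounds <- sort(c(bt, ba))
  if (length(bounds) > 1) {
    keep <- c(TRUE, diff(bounds) >= cfg$min_gap)
    bounds <- bounds[keep]
  }
  edges <- unique(c(0, bounds, total))
  k <- length(edges) - 1L
  out <- data.frame(start = edges[-length(edges)], end = edges[-1L],
                    label = NA_character_, mean_outer_temp = NA_real_,
                    mean_aqi = NA_real_)
  for (s in seq_len(k)) {
    i0 <- floor(out$start[s] * fs) + 1L
    i1 <- min(n, ceiling(out$end[s] * fs))
    mt <- mean(outer_temp[i0:i1])
    ma <- NA_real_
    if (!is.null(rel)) {
      in_seg <- rel$time >= out$start[s] & rel$time < out$end[s] &
        rel$reliable
      if (any(in_seg)) ma <- mean(rel$value[in_seg])
    }
    out$mean_outer_temp[s] <- mt
    out$mean_aqi[s] <- ma
    out$label[s] <- if (mt >= cfg$indoor_temp) {
      "indoor"
    } else if (mt < cfg$outdoor_temp) {
      "outdoor"
    } else if (!is.na(ma) && ma >= cfg$transit_aqi) {
      "transit"
    } else if (is.na(ma)) {
      "unknown"
    } else {
      "outdoor"
    }
  }
  class(out) <- c("zone_segments", "data.frame")
  out
}

#' Extract AQI samples from a record
#'
#' Convenience accessor building the (`time`, `value`, `accuracy`) sample
#' frame expected by [gate_by_accuracy()] and [segment_zones()] from the
#' outer side of a `dual_channel_record`.
#'
#' @param record A `dual_channel_record`.
#' @return Data frame with `time`, `value`, `accuracy`.
#' @export
aqi_samples <- function(record) {
  if (!inherits(record, "dual_channel_record")) {
    stop("`record` must be a dual_channel_record", call. = FALSE)
  }
  data.frame(time = record$time, value = record$outer$aqi,
             accuracy = record$outer$aqi_accuracy)
}
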