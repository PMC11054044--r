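#' Default duty-cycle power budget
#'
#' The per-component current-consumption table of the sensor node: each entry
#' gives the fraction of a 1-second operating cycle during which the
#' component draws its stated current, so `time_ratio * current` is the
#' entry's consumption in mA-seconds per cycle and the sum over entries is
#' the average current in mA. Ships as a plain CSV
#' (`extdata/power_budget.csv`) editable for other hardware; the
#' `consumption_masec` column carries the nominal per-entry consumption for
#' cross-checking.
#'
#' @return Data frame with `component`, `time_ratio`, `current_ma` and
#'   `consumption_masec`.
#' @export
#' @examples
#' average_current(default_power_budget())  # 1.8662 mA
default_power_budget <- function() {
  path <- system.file("extdata", "power_budget.csv",
                      package = "maskmonitor", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Average current of a duty-cycled budget
#'
#' @param entries Data frame with `time_ratio` (fraction of the cycle, in
#'   `[0, 1]`) and `current_ma` (mA, non-negative).
#' @return Average current in mA: `sum(time_ratio * current_ma)`; 0 for an
#'   empty table.
#' @export
average_current <- function(entries) {
  if (!all(c("time_ratio", "current_ma") %in% names(entries))) {
    stop("`entries` needs columns time_ratio and current_ma", call. = FALSE)
  }
  if (nrow(entries) == 0L) return(0)
  tr <- entries$time_ratio
  cu <- entries$current_ma
  if (any(!is.finite(tr)) || any(tr < 0 | tr > 1)) {
    stop("time ratios must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(cu)) || any(cu < 0)) {
    stop("currents must be non-negative", call. = FALSE)
  }
  sum(tr * cu)
}

#' Battery endurance
#'
#' @param capacity Battery capacity (mAh), non-negative.
#' @param avg_current Average current draw (mA), strictly positive.
#' @return Endurance in hours: `capacity / avg_current`. A 180 mAh cell at
#'   the default budget's 1.8662 mA lasts ~96.5 h, a working week.
#' @export
battery_life <- function(capacity, avg_current) {
  assert_scalar_num(capacity, "capacity", nonneg = TRUE)
  if (!is.numeric(avg_current) || !is.finite(avg_current) ||
      avg_current <= 0) {
    stop("`avg_current` must be strictly positive", call. = FALSE)
  }
  capacity / avg_current
}

#' Assemble a power budget
#'
#' @param entries Budget table, default [default_power_budget()].
#' @param capacity Battery capacity (mAh), default 180.
#' @return An object of class `power_budget`: list with `entries` (including
#'   a recomputed `consumption` column), `average_current` (mA), `capacity`
#'   (mAh) and `endurance` (h).
#' @export
power_budget <- function(entries = default_power_budget(), capacity = 180) {
  avg <- average_current(entries)
  entries$consumption <- entries$time_ratio * entries$current_ma
  structure(list(entries = entries,
                 average_current = avg,
                 capacity = capacity,
                 endurance = battery_life(capacity, avg)),
            class = "power_budget")
}

#' @export
print.power_budget <- function(x, ...) {
  cat(sprintf(paste0("<power_budget: %d components, average current ",
                     "%.4f mA, %g mAh battery -> %.1f h endurance>\n"),
              nrow(x$entries), x$average_current, x$capacity, x$endurance))
  invisible(x)
}
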