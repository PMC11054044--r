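#' Particle-counter size bins
#'
#' The six size ranges of the Lasair III 310C particle counter:
#' 0.3-0.5, 0.5-1, 1-5, 5-10, 10-25 and >25 um.
#'
#' @return Data frame with `bin_low_um` and `bin_high_um` (upper bound `Inf`
#'   for the open top bin).
#' @export
lasair_bins <- function() {
  data.frame(bin_low_um = c(0.3, 0.5, 1, 5, 10, 25),
             bin_high_um = c(0.5, 1, 5, 10, 25, Inf))
}

#' Particle number concentrations per size bin
#'
#' @param pnc Particle number concentration per bin (particles/m^3),
#'   non-negative, one value per bin.
#' @param bins Bin definition data frame (`bin_low_um`, `bin_high_um`);
#'   defaults to the six [lasair_bins()].
#' @param role `"ambient"` (free air) or `"behind_mask"`.
#' @param duration Sampling duration (s), default 60 (1 min counts).
#' @param flow_lpm Volume flow of the counter (l/min), used only for the
#'   low-count flag.
#' @return An object of class `particle_counts`.
#' @export
#' @examples
#' particle_counts(c(2e6, 1e6, 4e5, 1e4, 2e3, 0), role = "ambient")
particle_counts <- function(pnc, bins = lasair_bins(),
                            role = c("ambient", "behind_mask"),
                            duration = 60, flow_lpm = 30) {
  role <- match.arg(role)
  if (!is.numeric(pnc) || any(!is.finite(pnc)) || any(pnc < 0)) {
    stop("`pnc` must be non-negative finite concentrations", call. = FALSE)
  }
  if (length(pnc) != nrow(bins)) {
    stop("`pnc` must have one value per bin", call. = FALSE)
  }
  assert_scalar_num(duration, "duration", positive = TRUE)
  structure(list(bins = bins, pnc = as.numeric(pnc), role = role,
                 duration = duration, flow_lpm = flow_lpm),
            class = "particle_counts")
}

bins_match <- function(a, b) {
  isTRUE(all.equal(a$bins$bin_low_um, b$bins$bin_low_um)) &&
    isTRUE(all.equal(a$bins$bin_high_um, b$bins$bin_high_um))
}

#' Particle filtration efficiency per size bin
#'
#' For each bin, `PFE = (PNC_A - PNC_C) / PNC_A * 100` where `PNC_A` is the
#' ambient concentration and `PNC_C` the concentration behind the mask.
#' A bin with zero ambient count is flagged invalid (`NaN` efficiency); a bin
#' where the behind-mask count exceeds ambient yields a negative efficiency
#' with a warning flag rather than being clamped, since measurement variation
#' is itself information. Bins whose expected ambient count within the
#' sampled volume is below 10 particles are flagged `low_count` (Poisson
#' counting error dominates there).
#'
#' @param ambient A [particle_counts()] with role `"ambient"`.
#' @param behind A [particle_counts()] with role `"behind_mask"`.
#' @return An object of class `pfe_result`: data frame with the bin bounds,
#'   `pnc_ambient`, `pnc_behind`, `pfe` (percent, always <= 100) and logical
#'   flags `invalid`, `negative`, `low_count`.
#' @export
#' @examples
#' a <- particle_counts(c(1e5, 1e5, 1e5, 1e5, 1e5, 1e5), role = "ambient")
#' b <- particle_counts(c(6e3, 0, 1e5, 2e5, 1e5, 1e5), role = "behind_mask")
#' pfe(a, b)
pfe <- function(ambient, behind) {
  if (!inherits(ambient, "particle_counts") ||
      !inherits(behind, "particle_counts")) {
    stop("inputs must be particle_counts objects", call. = FALSE)
  }
  if (ambient$role != "ambient" || behind$role != "behind_mask") {
    stop("roles must be ambient and behind_mask, in that order",
         call. = FALSE)
  }
  if (!bins_match(ambient, behind)) {
    stop("bin definitions do not match", call. = FALSE)
  }
  a <- ambient$pnc
  c_ <- behind$pnc
  eff <- ifelse(a > 0, (a - c_) / a * 100, NaN)
  sampled_m3 <- ambient$flow_lpm / 1000 * ambient$duration / 60
  res <- data.frame(ambient$bins,
                    pnc_ambient = a,
                    pnc_behind = c_,
                    pfe = eff,
                    invalid = a == 0,
                    negative = is.finite(eff) & eff < 0,
                    low_count = a * sampled_m3 < 10)
  class(res) <- c("pfe_result", "data.frame")
  res
}

#' Compare two filtration-efficiency results per bin
#'
#' Difference report `prepared - reference` (percentage points per bin), e.g.
#' an electronics-embedded mask against its unprepared reference. Validity
#' flags propagate: a difference involving any flagged bin is flagged.
#'
#' @param reference,prepared `pfe_result` objects over the same bins.
#' @return Data frame with the bin bounds, `pfe_reference`, `pfe_prepared`,
#'   `difference` (points) and a propagated `flagged` column.
#' @export
compare_pfe <- function(reference, prepared) {
  if (!inherits(reference, "pfe_result") ||
      !inherits(prepared, "pfe_result")) {
    stop("inputs must be pfe_result objects", call. = FALSE)
  }
  if (!isTRUE(all.equal(reference$bin_low_um, prepared$bin_low_um)) ||
      !isTRUE(all.equal(reference$bin_high_um, prepared$bin_high_um))) {
    stop("bin definitions do not match", call. = FALSE)
  }
  data.frame(bin_low_um = reference$bin_low_um,
             bin_high_um = reference$bin_high_um,
             pfe_reference = reference$pfe,
             pfe_prepared = prepared$pfe,
             difference = prepared$pfe - reference$pfe,
             flagged = reference$invalid | reference$negative |
               reference$low_count | prepared$invalid | prepared$negative |
               prepared$low_count)
}
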