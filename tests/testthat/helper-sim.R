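## shared fixtures: all synthetic, built in code at test time

# a clean sinusoid starting at its minimum so every rising mean-crossing lies
# strictly inside the series
clean_breath_sine <- function(rate_per_min, duration = 60, fs = 10,
                              amplitude = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  -amplitude * cos(2 * pi * rate_per_min / 60 * t)
}

# detector configured with the noise-floor amplitude of a channel
pressure_detector <- function() detector_config(min_amplitude = 4 * 0.18)
temperature_detector <- function() detector_config(min_amplitude = 4 * 0.01)

# six-bin count set builders
ambient_counts <- function(pnc) particle_counts(pnc, role = "ambient")
behind_counts <- function(pnc) particle_counts(pnc, role = "behind_mask")
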