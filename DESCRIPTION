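Package: maskmonitor
Title: Signal Processing for Dual-Sensor Mask-Embedded Environmental Monitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wearable air-quality monitors embedded in
    protective face masks with one environmental sensor facing the wearer
    (inner) and one facing the ambient air (outer). Provides a scenario-scripted
    simulator of dual-channel sensor sessions (temperature, pressure, humidity,
    gas resistance, air-quality index), respiration-rate detection by
    moving-mean threshold crossing, a temperature/pressure source-selection
    state machine for fused respiration estimates, barometric (hypsometric)
    altimetry with floor-transition detection, per-size-bin particle filtration
    efficiency, air-quality-index classification and calibration gating,
    humidity-channel validity assessment, urban zone segmentation, and a
    duty-cycle power budget with battery-endurance estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
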