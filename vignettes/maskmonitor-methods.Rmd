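---
title: "Methods: respiration, fusion, altimetry and air-quality analysis for mask-embedded dual sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiration, fusion, altimetry and air-quality analysis for mask-embedded dual sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskmonitor)
```

`maskmonitor` analyses recordings from a wearable environmental monitor
embedded in a protective face mask, with one sensor facing the wearer's
airspace (*inner*) and one the ambient air (*outer*). This vignette explains
the models behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic-session generator does and does not
emulate, and the numerical choices that matter.

## The signal model

Each breath perturbs the in-mask microclimate: exhalation raises the local
pressure by tens of pascals and the local temperature by a few tenths of a
degree. The inner pressure channel sees the breath at full amplitude
(peak-to-peak ~20–40 Pa); the outward-facing channel sees a strongly
attenuated copy (<10 Pa). Temperature responds through the sensor's thermal
mass, which both *delays* the oscillation (~3 s behind pressure) and
*smooths* it: short flow stutters that split a pressure peak in two are
invisible in temperature. This asymmetry is the basis of the whole pipeline:
pressure is the more responsive breath sensor but is also sensitive to
barometric events (floors, doors, wind), while temperature is the more
stable breath sensor but is useless while the ambient temperature drifts.

## Respiration: moving-mean threshold crossing

`detect_breaths()` counts breaths as crossings of the signal through its own
centered moving mean. No low-pass pre-filter is applied; at 10 Hz sampling
the breath band is far below the Nyquist frequency and the moving-mean
comparison is itself the smoother.

Parameters (in `detector_config()`):

* `window` (s, default **5**) — the averaging window. It should be near one
  breath period so the mean tracks the baseline but not individual breaths.
  At the default the mean of a 12 breaths/min signal is attenuated to a few
  percent. The edges of the series use a shrinking window, so a constant
  series is its own mean.
* `min_breath_interval` (s, default **1.5**) — refractory period; caps the
  detectable rate at 40 breaths/min, above the 12–20 normal range, and
  prevents double counts.
* `min_amplitude` (channel units, default **0**) — the channel noise floor:
  a crossing only counts if the local peak-to-peak since the previous event
  reaches it. For quantization suppression use 4× the channel resolution
  (0.04 °C, 0.72 Pa); to reject breaths buried in noise use a multiple of
  the channel's RMS noise instead.
* `debounce` (s, default **0.3**) — a side change of the signal relative to
  the mean registers only once the new side persists this long. Without it,
  per-sample noise fabricates crossings where the signal grazes the mean
  (particularly at the falling edge, where the refractory period of the
  preceding true event has already expired). 0.3 s is well below the
  above-mean phase of a breath even at 40 breaths/min, so it cannot
  suppress a real breath; set 0 to disable.

Rate is defined as 60 × events / analysed duration, so it is exactly the
count on a 60 s window and a half-count granularity on 120 s windows.
Detection is invariant to constant offsets and to amplitude rescaling above
the noise floor, which is why per-session sensor bias is irrelevant here.

## Fusion: source selection by baseline stability

`fused_respiration()` partitions a session into evaluation windows
(default **60 s** long, advanced every **30 s**) and in each window measures

* the inner-temperature drift (°C/min), and
* the inner-pressure baseline drift, expressed per 10 s, on the
  breath-band-removed moving mean;

both as least-squares slopes of the moving mean with the shrinking-window
edges trimmed, so a pure ramp yields its exact slope (`drift_rate()`). The
decision rule (`select_source()`) is: temperature while
|temp drift| ≤ **0.1 °C/min**; otherwise pressure while
|pressure drift| ≤ **30 Pa/10 s**; otherwise *paused*, reporting no rate
and a waiting flag until either baseline settles.

The temperature threshold is the steady-state bound observed for this class
of recordings. The pressure threshold has to separate two regimes the data
exhibits: breath-band dynamics (the moving mean removes them almost
entirely, leaving drifts well under 10 Pa/10 s) and story transitions
(~55–60 Pa in ~10 s). 30 Pa/10 s sits between them: a single floor within a
60 s window produces a fitted slope of roughly 14 Pa/10 s — detectable by
the dedicated altimetry stage, but not enough to pause respiration — while a
continuous stair climb or an elevator does pause it. The evaluation cadence
(60/30 s) is a design choice: long enough that a window holds ≥6 breaths at
the lowest supported rate, short enough to follow indoor/outdoor
transitions. A source switch additionally requires the new decision to
persist for **2** consecutive evaluations (hysteresis), preventing chatter
when a drift hovers at threshold.

## Altimetry: linearized hypsometric conversion

`pressure_to_height()` uses Δh = (p_ref − p)/(ρg) with the density
ρ = p_mid/(R_d·T) evaluated at the mid-pressure, T = 288.15 K (standard
atmosphere) by default, R_d = 287.05 J/(kg·K), g = 9.80665 m/s². Over
building scales the linear form agrees with the exponential barometric
formula to better than 0.1% (a property test verifies this up to
|Δp| = 200 Pa), and it is exactly antisymmetric in (p, p_ref). Absolute
altitude is out of scope: the embedded device carries an uncalibrated offset,
so only relative heights are reported.

`detect_floor_changes()` removes the breath band with a short moving mean
(default **4 s**), takes a centered difference of that baseline over a
**15 s** span, and thresholds it at **40 Pa**. Each above-threshold run
yields one event at the extremum of the difference; the pre/post baseline
pair is converted to a signed height. The 15 s span is deliberate: it must
cover one full floor ramp (~10 s) *plus* the smoothing transient, or the
difference never sees the entire step (a 10 s span tops out near half the
per-floor signature and would sit below its own threshold), yet it must stay
shorter than the spacing of consecutive flights so two floors remain two
events. The 40 Pa threshold is above any breath leakage through the 4 s
smoother (worst case ~30 Pa for a 40 Pa-p2p breath at 6 breaths/min) and
below the 55–60 Pa one-floor signature.

## Filtration efficiency

`pfe()` implements PFE = (PNC_A − PNC_C)/PNC_A × 100 per size bin of the
particle counter (six bins: 0.3–0.5, 0.5–1, 1–5, 5–10, 10–25, >25 µm).
Three policies matter:

* a bin with zero ambient concentration has no defined efficiency → `NaN`
  plus an `invalid` flag;
* a behind-mask count exceeding ambient gives a *negative* efficiency with a
  `negative` flag — not clamped to zero, because embedded-vs-reference
  comparisons legitimately produce small negative differences and clamping
  would hide them;
* bins whose expected ambient count in the sampled volume (flow × duration)
  is below 10 particles carry a `low_count` flag, since Poisson counting
  error dominates there.

PFE is scale-invariant in the absolute concentration, which is why the
method tolerates day-to-day ambient variation in the 1–5 × 10⁷/m³ range.

## Air quality, humidity and zones

`classify_aqi()` maps 0–500 onto seven classes. The printed class table
of the sensor's documentation contains an overlapping range for "severely
polluted"; the package resolves it to 251–350, the only choice that keeps
the classes contiguous, and implements ">351" as 351–500 so every value in
range has exactly one class.

`gate_by_accuracy()` partitions AQI samples by the stack's calibration
status (0–3); the default reliability threshold is status ≥ 2. The
simulator's default settling schedule reaches status 2 after 31 min and 3
after 36 min, reflecting the more-than-half-an-hour settling the hardware
exhibits.

`humidity_validity()` flags the inner humidity channel invalid from the
first time it sustains ≥ 95 %rh for 60 s. The sustain requirement makes the
flag robust to single-sample spikes.

`segment_zones()` finds change-points with the same centered-difference
machinery as the altimetry stage, applied to the smoothed outer temperature
(step ≥ 3 °C) and to the reliable AQI stream (step ≥ 50); differences that
straddle unreliable AQI samples are discarded, so pre-calibration AQI can
never create a boundary. Segments are labeled by mean outer temperature
first (≥ 26 °C indoor, < 24 °C outdoor — in-mask readings settle near
22–23 °C on a winter street and near 30 °C indoors) with reliable AQI as
secondary evidence (intermediate temperature + mean AQI ≥ 120 → transit;
intermediate temperature with no reliable AQI → unknown). Temperature is
primary because it is always available, whereas AQI is gated.

## Power budget

`average_current()` sums duty-ratio × current over the component table; the
shipped default table (`default_power_budget()`) describes the node: the two
environmental sensors dominate (1.8 mA continuous), radio and ADC events are
duty-cycled to microamp-scale contributions, and the weighted sum is
1.8662 mA. `battery_life()` is capacity/current; endurance is linear in
capacity and inverse in current by construction.

## The synthetic-session generator

`simulate_session()` is a first-class, tested component, not a fixture. It
emulates, per sample at 10 Hz (configurable):

* segment temperatures approached with first-order settling (outer τ = 20 s,
  inner τ = 40 s, inner settling 1 °C warmer from exhalation);
* a breath oscillation of scripted rate with full amplitude on the inner
  pressure (default p2p 30 Pa), attenuated on the outer (default 5 Pa);
  optional *stutters* add a second-harmonic component to randomly chosen
  breaths, splitting the pressure peak without affecting temperature;
* the temperature oscillation as the **stutter-free fundamental of the
  breath drive evaluated `temp_lag` seconds in the past** (default 3 s).
  A causal first-order low-pass cannot realize a 3 s group delay at breath
  frequencies (its phase delay saturates at a quarter period, ~1.25 s at
  12 breaths/min), so the thermal channel is modeled as a pure transport
  delay of the fundamental: this reproduces both the measured lag exactly
  (the cross-correlation between detrended temperature and pressure peaks
  at 3 s ± 1 sample) and the inertia-driven smoothing (harmonics and
  stutters absent);
* stairs segments ramping the barometric baseline by 57.5 Pa (the centre of
  the 55–60 Pa per-floor band) over 10 s per flight, with a 12 s landing
  pause between flights — long enough for the smoothed baseline to settle so
  consecutive flights are distinct events;
* inner humidity following an exponential approach from 40 %rh toward
  99 %rh with τ = **550 s**. Together with the admissible per-session
  humidity bias (±1.5 %rh) this keeps the 95 %rh saturation crossing inside
  the 20–30 min window for every bias draw (21.7–29.0 min analytically);
  a 500 s constant would allow worst-case crossings just under 20 min;
* outer humidity as attenuated ambient (default factor 0.4: the mask fabric
  captures moisture, so 80–100 %rh ambient reads 30–40 %rh);
* AQI (outer side only — the inner airspace is permanently "polluted" by
  exhalation, so no inner AQI is ever computed) relaxing toward the scripted
  segment level (τ = 60 s) with a bounded AR(1) walk on top, clamped to
  [0, 500], and an accuracy status stepping 0→1→2→3 at 5, 31 and 36 min;
* gas resistance oscillating with the breath, ~10 kΩ p2p outer and ~3 kΩ
  p2p inner around 100/50 kΩ baselines;
* measurement error as a constant per-session bias per channel and side
  (uniform within half the accuracy bound: ±0.25 °C, ±6 Pa, ±1.5 %rh) plus
  per-sample Gaussian noise truncated at the bound with realistic RMS
  magnitudes (0.01 °C, 1.2 Pa, 0.1 %rh). Accuracy bounds of this sensor
  class are error *budgets* dominated by slowly varying bias; modeling them
  as white noise would exceed the observed peak-to-peak bands outright
  (±12 Pa white noise is incompatible with an outer breath p2p under
  10 Pa);
* quantization of every channel to the sensor resolutions (0.01 °C,
  0.18 Pa, 0.008 %rh).

Everything is driven by one integer seed; identical inputs produce
bit-identical records, and the generator truth (breathing model, stutter
cycles, scripted floor events with their hypsometric heights, segment
boundaries) rides along in `meta`.

**What it does not emulate** — and hence what passing tests do not show
about real data: motion and wind pressure artifacts, mask-fit leakage and
its time variation, sensor self-heating transients, coughing/talking,
irregular or varying breath rates within a session, barometric weather
drift, and the real (proprietary) mapping from gas resistance to AQI — the
simulator emits AQI directly. Validation on synthetic sessions demonstrates
that the estimators are correct for the documented signal structure, not
that the structure is a complete model of field recordings.

## Numerical choices and degenerate inputs

Moving means are computed from cumulative sums (exact for these magnitudes)
with centered, shrinking windows; a window must span ≥ 2 samples and no more
than the series. Drift fits trim the shrunken edges so ramps are recovered
exactly. Constant series give zero events and rate 0 (not an error); series
shorter than two detector windows, records shorter than one evaluation
window, and stairs segments too short for their flights are errors.
All-side-of-mean runs shorter than the debounce never register. Pressures
outside the 300–1100 hPa sensor range are rejected everywhere. Session CSVs
store seconds-from-start with fixed decimal formats chosen to be lossless at
the sensor resolutions; on read, both sides are aligned to the header
clock, missing samples become flagged `NA` rows, and genuinely different
per-side rates are an error.

## Problem sizes

The test-suite simulations use 2-minute sessions for rate recovery (rates
6–20 breaths/min × 20 seeds), 3.5-minute stair sessions (20 seeds), and one
55-minute demo walk for the AQI/humidity/zone timings; these sizes give
sub-breath-per-minute rate granularity and several times the settling
constants involved, and the whole suite runs in seconds.

## Known limitations

* The detector assumes near-constant rate within a window; strongly
  irregular breathing yields a meaningful count but a coarse "rate".
* The fusion pause threshold for pressure (30 Pa/10 s) is a design default
  between the two documented regimes, not a measured constant.
* Altimetry assumes the standard-atmosphere temperature in the density; a
  ±15 K error changes heights by ~5%, within the method's stated 10%
  tolerance but not negligible.
* Zone labels rest on fixed temperature bands appropriate for cold-season
  urban walks; summer scenarios need different `zone_config()` thresholds.
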