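---
title: "Calibrating and analysing a low-cost PM2.5 sensor network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and analysing a low-cost PM2.5 sensor network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmsensornet)
```

## The measurement problem

Optical low-cost PM2.5 sensors count particles by scattered light and
convert counts to mass with a fixed size-distribution assumption
(`PM2.5 = 0.518 + 0.00274 × count` in hppcf for the sensor model emulated
here). Two systematic effects dominate their error budget:

1. **Sensor-to-sensor offsets.** Each unit has its own effective gain and
   offset. These are stable over months, so they can be removed by
   collocation: run all sensors side by side, regress each on the network
   mean, and invert the fitted line.
2. **Hygroscopic growth bias.** In humid air, water uptake enlarges
   hygroscopic particles and inflates scattering per unit dry mass.
   Regulatory beta-attenuation monitors heat their inlet and report dry
   mass; the sensor does not. The bias is therefore shared by all sensors
   and grows with the absolute water content of the air, for which dew
   point is the natural index.

The package separates these: collocation correction makes the network
*internally* consistent (precision); comparison against reference monitors
with meteorological covariates quantifies the remaining *external* bias
(accuracy). No humidity correction is applied to the data — the humidity
effect is characterised, not removed, mirroring standard practice when the
goal is spatial comparison between identically-biased sensors.

## Data model and completeness rules

Minute records are averaged to hours labelled by interval start
(half-open `[t, t+1h)`), requiring 75% completeness: at least 45 of 60
valid minutes, otherwise the hour is missing (the minute count is always
reported). Negative concentrations are invalid and are dropped, not
clipped, with a QC count. Days require the same 75% fraction — at least 18
of 24 valid hours. The hourly rule is the campaign's stated convention; the
daily threshold is this package's choice, made once for consistency with
the hourly fraction, since no daily rule is stated anywhere. Day boundaries
follow the local standard time of the study region (`Etc/GMT+8` by
default, configurable).

All pairwise statistics align two series on their common valid timestamps
first; nothing is interpolated.

## Collocation calibration

For each collocation period the hourly network mean is computed over
sensors reporting that hour (default threshold: 75% of the sensors
present), *including* the sensor under evaluation — this matches the
construction of the published precision tables; a leave-one-out variant
would shrink slopes by about 1/n and is easy to derive from the fits.
Each sensor is regressed (OLS) on this mean; the fit reports slope,
intercept, Pearson R², the RMSE of the raw sensor-minus-mean differences,
and the hour count. Fits with fewer than 24 overlap hours are invalid
(half of the smallest collocation sample in the motivating campaign).

The correction factor averages the pre- and post-period coefficients;
when the post fit is invalid the pre coefficients are used alone
(`source = "pre_only"`). The correction `(raw − intercept)/slope` is exact
for affine relationships: fit-then-correct recovers an affinely
transformed series to machine precision, and R² against any reference is
invariant under it (both are asserted in the test suite).

**Drift** is evaluated by propagating the levels 5, 10, 20, 30, 40 and
50 µg/m³ through both periods' regressions and reporting the change in
µg/m³ and percent. The percent denominator is the pre-period *reading*,
the most literal interpretation; because summary fractions ("share of
cases under 10%") are sensitive to this choice, the nominal-level
denominator is available via a flag.

**Coefficient of variation** follows the convention of per-hour
across-sensor sample SD divided by the across-sensor mean, averaged over
hours (zero-mean hours skipped and counted). This is the convention of the
comparison literature the campaign cites; it is stated here because the
campaign itself does not define it.

## Meteorology

Dew point is computed in two steps chosen to be mutually consistent:
vapor pressure `VP = RH/100 × 6.11 × 10^(7.5 T/(237.3 + T))` hPa, and the
base-10 Magnus inversion
`Td = (237.3 log10 VP − 186.52)/(8.29 − log10 VP)`.
The saturation constants are fixed by the inversion's own constants
(237.3 appears in both; `8.29 ≈ 7.5 + log10 6.11`), making the round trip
`Td(VP(T, 100%)) = T` close to within 0.1 °C across −10…40 °C. A base-e
reading of the same inversion breaks the round trip by more than 1 °C —
the test suite demonstrates this, which is why base 10 is the only
defensible convention.

## Accuracy against reference monitors

The reference (hourly BAM-like or daily filter-based series) is the
response and the corrected sensor a predictor, so "how much does
meteorology explain of what the sensor misses" is read directly off the
adjusted R² ladder: sensor only; plus one of temperature, dew point, RH,
wind speed; all four; all four plus squares and all pairwise cross terms
(k = 1 + 4 + 4 + 6 = 15). Wind direction is excluded throughout. Adjusted
R² uses `1 − (1 − R²)(n − 1)/(n − k − 1)`. Single-covariate rows are
linear only, and all models include an intercept — both are unstated in
the motivating analysis and fixed here as conventions. Collinear terms are
dropped with a warning rather than failing the fit.

## Spatial statistics

The coefficient of divergence for aligned series x, y over p pairs is
`sqrt(mean(((x_i − y_i)/(x_i + y_i))²))`, in [0, 1], with 0.2 the
conventional heterogeneity threshold (boundary value 0.2 counts as
heterogeneous). Pairs summing to zero are undefined and skipped with a
count; negative values — possible at near-zero concentrations after linear
correction — are likewise skipped, because the statistic is only defined
for nonnegative concentrations and negative entries would break its upper
bound. Hourly matrices use corrected hourly values; daily matrices use
daily means built under the 18-of-24 rule. Minimum pairwise overlaps
default to 72 hours / 14 days.

Distances are great-circle (haversine, R = 6371 km). Moran's I uses
row-standardised weights (inverse distance by default, k-nearest
available — the weighting is a package convention, as none is stated in
the motivating analysis) with a permutation p-value; the implementation is
matrix-algebraic and is checked against a loop-written double-sum oracle
to 1e−12.

Group comparisons: the Welch unequal-variance t-test pools all values per
community group; the rank-sum test runs per cross pair of sites with raw
p-values (plus a Holm-adjusted column, since nine simultaneous pairs
invite multiplicity questions). Exact rank-sum p-values are verified
against full enumeration of rank assignments for group sizes up to six.

## Emissions-inventory linkage

Sites map to half-open 4×4 km cells (boundary points to the lower-left
cell). Per cell and day type, only hours in which *every* member site
reports enter the cell mean — sites hosting several sensors are first
collapsed to a site-hour mean. The increment is the cell mean minus the
lowest cell mean of the same day type, so exactly one cell per day type
is the zero-increment background; a fixed-quantile background is
available by flag. Whether the background should instead be global across
day types is genuinely open; per-day-type is the default because weekday
and weekend regressions are reported separately. Increments are regressed
on inventory emissions per day type; R² is invariant to emission units.

## The synthetic campaign generator

The generator exists so every stage is testable without field data. Its
defaults *are* the emulated study conditions: 19 sensors, 15 sites in six
communities (three EJ), a 7-day pre-collocation, 62-day deployment with
3 + 3 sensors at the two reference sites, and 32-day post-collocation.

- **Truth field.** A shared regional log-normal baseline (day-scale AR(1),
  φ = 0.6, σ = 0.4; hour-scale AR(1), φ = 0.95, σ = 0.1; median
  9 µg/m³) times a diurnal factor with the afternoon minimum near 0.55
  and a nocturnal peak near 1.85, rising from 16:00 — night/afternoon
  ratios of about 3, as observed in wintertime valley conditions —
  times transient log-normal site noise with exponential spatial
  correlation (σ = 0.15, length 8 km), times a small persistent per-site
  source-strength factor (log-normal, σ = 0.025, independent across
  sites), plus nocturnal spike events (probability 0.05 per site-night
  -hour, mean 8 µg/m³). The persistent factor is what gives grid cells
  genuinely different long-run means for the emissions linkage; it is
  kept spatially independent and small so that community group means
  remain exchangeable when `ej_effect = 0` and the Welch null calibration
  holds by construction.
- **Meteorology.** Seasonal and diurnal harmonics with AR(1) noise:
  temperatures around 5–14 °C, RH high at night (most night hours above
  85%), light winds, dew points mostly 2–10 °C.
- **Sensor forward model.** `m = slope × (g(dew) × true) + intercept +
  noise`, floored at zero, with growth
  `g = 1 + 0.2 × max(0, dew − 4 °C)` — unbiased below 4 °C dew point and
  a factor of 3 at 14 °C, spanning the observed 1–3× bias range. Growth
  multiplies the *aerosol*, not the sensor's output: water uptake is a
  property of the particles and is common to every collocated sensor, so
  the sensor-vs-network-mean regression stays exactly affine and
  collocation calibration remains valid in humid conditions — precisely
  what the motivating campaign observed. An RH-power-law growth variant
  is available; no test depends on the curve's shape beyond monotonicity.
  Per-sensor slopes and intercepts are drawn uniformly from the observed
  collocation ranges (0.78–1.64 and −3.2…2.6 µg/m³). Noise (σ = 1 µg/m³)
  is added per emitted record — per minute in minute resolution, per hour
  in the faster hourly resolution used for replicated experiments — and
  counts are emitted through the exact retrieval inverse so either column
  can be ingested. Minutes are dropped independently at 5%.
- **References.** The hourly BAM-like series is truth times
  `1 + N(0, 0.11)` (half the monitor's ~22% stated precision), floored at
  zero; the daily filter series is near-truth (σ = 0.3 µg/m³).
- **Emissions grid.** Cell emissions are an affine function of the cell's
  realised long-run truth increment, distorted multiplicatively
  (relative σ = 0.4). Zero distortion makes the increment–emissions
  regression exact; the default distortion puts the measured-data R²
  in the moderately-strong range seen in practice (the test suite checks
  the replicate average lies in (0.4, 0.9)).

What the generator deliberately does **not** emulate: atmospheric
transport and chemistry (spikes are statistical, not advected), secondary
aerosol formation, instrument drift within a phase, correlated sensor
failures, or a persistent spatial gradient aligned with community
boundaries. Passing tests therefore demonstrate that the *methods* behave
correctly on data with the assumed structure; they cannot certify any
particular field deployment.

## Numerical choices and degenerate inputs

- OLS everywhere via `lm`; zero variance in a regressor is an error for
  calibration fits and a dropped-term warning in the meteorological
  ladder.
- Correction factors are carried at full precision; comparisons with
  printed tables round to two decimals only at comparison time. Printed
  half-unit ties (e.g. an average of 0.945 printed as 0.94) are accepted
  at half a printed unit.
- Aggregation uses exact integer hour arithmetic (`floor(t/3600)`); the
  same input in any order yields identical output.
- Moran's I requires at least four sites and non-constant values; COD
  with no usable pairs returns NA with a warning rather than an error so
  that one degenerate pair does not abort a matrix.
- Seeds: every stochastic routine takes an explicit seed or runs inside
  `simulate_campaign(seed = ...)`; identical seeds give byte-identical
  pipeline outputs.

## Problem sizes used by the test suite

Module tests run reduced phase lengths (3–14 day phases) of the same
generative structure; the bias-recovery and meteorological-ranking checks
use the full default campaign (one minute-resolution and one
hourly-resolution run); the null-calibration check uses 50 hourly-
resolution replicates of the full campaign. These sizes were chosen so
the statistical assertions are sharp (e.g. ±2% slope recovery needs a few
hundred collocation hours) while the whole suite stays interactive.

## Known limitations

- The calibration normalises to the network mean, not to a reference
  instrument; an absolutely biased but internally consistent network
  stays biased after correction (by design, as in the motivating study).
- The EJ comparison pools hourly values; its p-value treats hours as
  exchangeable units. On strongly autocorrelated data this is
  anti-conservative in general — here the shared regional baseline makes
  the pooled test conservative instead, which the null-calibration test
  verifies for this data structure, but the caveat stands for other
  structures.
- Five sensors of the motivating campaign used pre-only corrections; only
  the three identifiable from the printed table are marked as such in the
  fixture (the other two are indistinguishable from averaged rows at
  printed precision).
- The published "4.6% average slope change" and "6.9% slope-deviation SD"
  could not be reproduced unambiguously from the printed table under any
  obvious definition; the pipeline reports drift under the documented
  definitions instead and makes no claim to match those two numbers.
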