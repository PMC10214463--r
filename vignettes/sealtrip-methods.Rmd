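---
title: "Methods: dive processing, morphometrics and bioenergetics in sealtrip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dive processing, morphometrics and bioenergetics in sealtrip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealtrip)
```

`sealtrip` turns raw biologging records from a deep-diving phocid — a depth
time series, a location track, jaw-motion event timestamps and paired
morphometry — into dive statistics, behavioural summaries and an energy
budget. This vignette documents the models and conventions behind each
stage, the parameters that matter, and what the synthetic validation does
and does not demonstrate.

## Dive processing

**Zero-offset correction.** Pressure transducers drift, so "surface" is
rarely 0 m in a raw record. `zeroOffsetCorrect()` estimates the surface
baseline as the rolling 2nd percentile of depth in 30-minute windows
overlapping by half, interpolates the window-centre estimates linearly, and
subtracts. Two numerical choices deserve note:

* a *low percentile* rather than the minimum, so single negative noise
  spikes cannot drag the baseline down;
* a short rolling minimum (two windows each side) applied to the
  window estimates before interpolation. A window that falls entirely
  within a dive longer than the window sees no surface at all, and its
  percentile would be hundreds of metres deep; the rolling minimum lets it
  inherit the surface estimate of its neighbours. The cost is a small
  downward bias under steep drift; at realistic drift rates (metres per
  week) the surface residual is ~0.2 m with 0.2 m sensor noise.

Residual negative depths are clipped to zero. Records shorter than one
window are rejected rather than guessed at.

**Dive detection.** A dive is a maximal run of samples deeper than the 2 m
surface threshold whose maximum depth reaches 15 m and whose duration
reaches 32 s (four samples at the 8-s standard interval). These thresholds
are field-standard for deep-diving phocids, not tuned values: an elephant
seal's shallowest real dives are tens of metres, so results are insensitive
to them over a wide range, and all three are exposed as arguments. Dive
boundaries are taken one sample outside the submerged run (the samples
bracketing the surface crossings), which puts start/end within one sample
of the true surfacing moments; the post-dive interval (PDI) is the gap from
a dive's end to the next dive's start. Records are assumed gap-free; a
record with sampling gaps should be split and the segments processed
independently, since a PDI spanning a gap is undefined.

**Per-dive statistics.** The bottom phase is the span of samples at ≥ 80 %
of the dive's maximum depth — a common convention, configurable because no
single definition is universal. Descent rate is (first bottom-phase depth −
surface depth)/elapsed time, ascent rate symmetric; wiggles are bottom-phase
local maxima with topographic prominence ≥ 5 m, counted by an explicit
walk-out prominence scan. Dives of fewer than three samples get zeroed
statistics and a `flag_degenerate` marker rather than `NaN`s.

**Subsampling.** Records from tags with finer native rates are decimated to
a common 8-s grid by keeping every k-th sample (the first sample retained);
non-integer ratios are an error rather than silently resampled.

## Track geometry and day/night

Tracks are assumed already quality-filtered (state-space filtering of Argos
error is a solved problem and out of scope). `interpolateTrack()` is linear
in latitude/longitude at hourly spacing — at ~70 km/day the difference from
great-circle interpolation is metres. Distances use the haversine formula
on a 6371.0 km sphere (via `geosphere`). Antimeridian-crossing tracks are
not supported.

Solar elevation uses the Julian-century series of the NOAA solar
calculator: solar declination and the equation of time feed the hour angle
and the spherical triangle. Accuracy is better than 0.1° against an
independent ephemeris, far inside what day/night classification needs. The
elevation is *geometric*: no atmospheric refraction, so the day/night
boundary is the 0° geometric horizon (refraction would shift it < 1°). Each
dive is located by linear interpolation of the track at its start time —
the start was chosen (configurably) because a single representative instant
is needed and dives are short relative to the diel cycle — and flagged day
when elevation is strictly greater than 0°. A dive at exactly 0° is night;
the tie is unobservable in practice but the rule is fixed and documented.
Dives outside the track's time span stay unlocated and are excluded from
day/night splits.

## Truncated-cones morphometrics

The body is reconstructed from girths measured at six evenly spaced
stations along the standard length: seven circular frusta span ankles to
ears, divided at the stations, and variants close the ends —

* `min`: frusta only;
* `best`: frusta + a cone from ears to nose (the head);
* `max`: best + a cone from ankles to tail tip.

Adding a pointed cone adds area proportionally faster than volume, so
SA/V(min) ≤ SA/V(best) ≤ SA/V(max) — asserted empirically over a thousand
random morphometries in the tests.

Two geometric details are underdetermined by measurement and fixed here as
package conventions: the ear and ankle boundary positions are extrapolated
half a station spacing beyond the outer stations, and their radii (no girth
is measured there) default to 0.70 and 0.60 of the adjacent station radius.
Those fractions are anatomically sensible for an elephant seal's thick neck
and tapering hindquarters and keep the reconstruction consistent with a
cylinder benchmark (an equal-girth record reconstructs to within ~4 % of
the cylinder volume over the coned span); both are exposed as arguments.

Body composition: the blubber shell is the volume between the outer frusta
and frusta deflated by the per-station blubber thickness (dorsal and
lateral measurements averaged — the combination rule is not standardised,
so the mean is used and documented). Shell volume × 940 kg m⁻³ (lipid-rich
blubber) gives blubber mass; dividing by body mass gives the raw adipose
fraction, passed through a linear calibration slot. The shipped calibration
is the identity — the calibration to body-water composition belongs to a
study's own validation data, and all composition values anchored to
published numbers enter through `compositionSplit()` (printed fractions)
instead. Reported adipose/FFM masses use the integer-kg convention
(adipose rounded, FFM the complement) so printed pairs always sum to the
printed mass; raw values are retained alongside.

The fasting mass correction moves a measured mass to the at-sea endpoint
of a trip: mass-specific daily fasting loss `1.2209 + 0.01329 × mass`
kg/day times days fasting. In `tripSummary()` the correction is
*subtracted* from a departure-stage measurement (the animal keeps fasting
between measurement and departure) and *added* to an arrival-stage one.

## Bioenergetics

All constants live in an `EnergyConstants` object: lean tissue is 27 %
water-free at 17.99 MJ/kg dry; lipid 90 % at 39.33 MJ/kg; baseline
post-breeding FMR 90.1 kJ kg⁻¹ d⁻¹; blood volume 20.2 % of body mass
(1 kg ≡ 1 L); fever raises metabolic rate 10–12.5 % per °C. Internal math
is full precision; rounding to printed conventions happens only at the
reporting layer.

`fmrCost()` integrates FMR × m(t) with mass declining linearly between the
trip endpoints — the exact integral is the trapezoid, FMR · D · (m₀+m₁)/2.
`feverCost()` defaults to holding mass constant at its value entering the
febrile window, the natural reading for a two-week episode early in a trip;
a linear trajectory is available via `massEndKg`. One published arithmetic
chain is internally inconsistent at the ~2 % level (a projected post-moult
mass of ~189 kg versus the 245 − 59.25 = 185.75 kg the stated rate and
duration give); `fastingProjection()` reports the arithmetic result and
does not guess at the discrepancy.

## Foraging metrics

Jaw-motion events are consumed as timestamps (detecting them from raw
acceleration is upstream, prior-work territory). Daily bins are anchored at
*trip start*, not civil midnight, so day indices align with day-of-trip
plots. Percent time foraging needs an operational definition of a foraging
dive; the package uses "contains ≥ k events" (k = 1 by default, exposed),
a documented surrogate for accelerometer-based dive classification, and
computes 100 × (foraging dive time)/(dives + PDIs). Event depths are linear
interpolations of the depth record; binned densities are normalised to
integrate to exactly 1.

## Summaries, densities and trends

`tripSummary()` computes per-trip metrics and grand means ± SD of the
diving statistics, overall and split day/night over located dives only.
`diveKDE2d()` is a product-Gaussian kernel density on a regular 64 × 64
grid with per-axis Scott's-rule bandwidths (σ · n^(−1/6)) and a 4-bandwidth
grid margin so the surface integrates to 1 within 1 %; it is checked
against a direct kernel-sum oracle at random grid nodes. Degenerate
(zero-variance) axes are an error. `cumulativePdiCurve()` is the empirical
CDF with an optional zoom into the top quantile band, where extended
surface intervals separate a sick record from healthy ones.

`trendSmooth()` fits LOESS — local linear regression with tricube weights
over the nearest ceiling(span·n) points, span 0.3 by default — with a
seeded bootstrap (200 resamples) for pointwise 95 % bands. A plotting-layer
GAM would serve equally; LOESS was chosen as a transparent, dependency-free
smoother whose local-linear form is exactly faithful to linear trends (the
property the tests exploit), and no reported quantity depends on smoother
internals. Spans leaving fewer than four points per fit are rejected.

## The synthetic-trip generator

`simulateTrip()` is the package's validation instrument: every downstream
statistic can be checked against exact ground truth. It emulates the
post-breeding trip of an adult female elephant seal:

| parameter | default | rationale |
|---|---|---|
| dive duration | 22 ± 4 min | healthy dives run 20–40 min; cohort mean ~21 min |
| max depth | 570 m day / 490 m night ± 80 | diel vertical migration of prey; day > night |
| PDI | log-normal, mean 2 min, 0.5 min floor | surface intervals are ~2 min and right-skewed |
| descent / ascent | 1.3 / 1.2 m s⁻¹ | cohort means |
| wiggles | 0.5 per bottom-minute | typical pursuit rates |
| jaw events | 1250/day healthy, 300/day sick | healthy seals make 1000–1500 attempts/day; sick < 500 |
| illness PDIs | log-uniform 3–30 min in the window | the sick regime's extended surface intervals |
| late extended PDIs | p = 0.02/dive, 30–200 min | rare, highly extended later intervals |
| sensor drift / noise | 0 m, 0.2 m | drift off by default; noise at tag scale |
| displacement | 70 km/day | ~5500 km over ~79 days |

Dives are trapezoids: constant-rate descent to a shoulder depth, a bottom
phase carrying a sinusoid whose peaks reach the dive's maximum depth (one
peak per wiggle, amplitude ≤ 20 m, period kept above six samples so peaks
are resolvable), constant-rate ascent. Depth, duration and the implied
bottom time are mutually consistent by construction; a dive is shallowed if
its drawn duration cannot accommodate its drawn depth at the configured
rates, and configurations whose *mean* duration is infeasible are rejected
outright. The illness window is day-indexed with hard boundaries at day
start (active on days `start ≤ d < end`, day 0 being the first 24 h).
Corruption — linear sensor drift plus Gaussian noise — is applied after the
truth table is recorded, so truth is exact. A `diveDurationTrend` knob
(min/day drift of the mean) reproduces the declining-duration signature of
a deteriorating animal.

The distributional *forms* (log-normal PDIs, log-uniform illness PDIs,
Gaussian depths/durations, Poisson daily event counts placed uniformly in
bottom phases) are stand-ins — no published source reports them — so no
validation here asserts anything sharper than ranges, rates and moments
about them. The track is a kinematic out-and-back random walk; it has
correct distances and timing but no oceanography. The generator also omits,
deliberately: haul-outs, gaps, drift dives and benthic dives, 3-D movement,
prey fields, and accelerometer waveforms. Passing the synthetic recovery
suite therefore demonstrates that the *processing chain* is correct and
self-consistent at realistic signal scales — not that it is robust to every
artefact of real tag data.

The paired morphometry is built by `syntheticMorphometry()`: girths follow
a fusiform profile scaled so the cones volume matches mass at a whole-body
density of 1030 kg m⁻³, and blubber thickness is solved by `uniroot` (to
1e-10) so the blubber-shell composition hits the target adipose fraction —
departure 294 kg at 24.7 %, arrival 245 kg at 18.3 %, the documented
endpoints of the study animal. These records are synthetic stand-ins, not
the animal's measurements.

## Problem sizes and determinism

The validation suite runs 10–25-day trips (~600–1500 dives) for module
tests and one 80-day trip (~4800 dives, 864 001 samples at 8 s) for the
full recovery check, completing in well under a minute; `scripts/acceptance.R`
re-runs the headline computations in a few seconds. Every stochastic step
is seeded: `simulateTrip()` is bit-for-bit reproducible for a fixed seed,
jaw events use a stream derived from the same seed (so standalone and
in-trip calls agree), and the bootstrap in `trendSmooth()` takes an
explicit seed.

## Known limitations

* PDIs across sampling gaps are undefined; gap handling is splitting, not
  imputation.
* The ZOC baseline biases slightly low under steep drift (> ~5 m/day)
  because of the rolling-minimum step.
* The truncated-cones end radii and the dorsal/lateral blubber combination
  are conventions, not measurements; both are configurable and any
  absolute composition comparison should use a study-specific calibration.
* Day/night classification evaluates one instant per dive; dives spanning
  twilight get a single label.
* The cohort-style summary reports per-trip means ± SD; pooled-dive RMSE
  conventions differ between published tables and are not reproduced
  exactly.
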