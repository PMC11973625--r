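---
title: "Methods: reef-scale larval transport, residence time, and slack-current detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reef-scale larval transport, residence time, and slack-current detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaflow)
```

`larvaflow` analyses the dispersal of coral spawn and larvae at the scale of
a single reef system. This vignette is the package's account of the science:
the transport model and its assumptions, the retention and validation
statistics, the changepoint machinery, what the synthetic data generators do
and do not emulate, and the numerical choices a user should know about.

## Coordinates, grids and fields

All computation happens on a local tangent plane in metres, anchored at a
lon/lat origin through an equirectangular projection (`lonlat_to_local()`,
`local_to_lonlat()`). Over domains of order 10 km the planar distortion is
far below the 50-m cell size, which is why no projection library is needed.

A `current_field` stores `u,v` (m/s, east/north) on a regular grid over
`(time, depth layer, y, x)` with a per-cell mask (`water`,
`land_or_shallow_reef`, `open_boundary`). Defaults mirror the reef-scale
modelling practice the package emulates: 50-m cells, a 12-min (720 s) output
step, near-surface layers at 0.25–1.95 m for buoyant spawn and 3.6 m for
larval delivery. Velocities between cell centres are interpolated bilinearly;
land cells are excluded from the stencil and the remaining weights
renormalised, so flow never "bleeds" out of the coastline; depth uses the
nearest stored layer (particles are depth-bound, see below); time is linear
between stored steps.

## The synthetic current generator

`build_tidal_field()` produces the regime in which the downstream analysis is
best behaved and against which it is tested: a sinusoidal tidal current of
amplitude `tidal_amp` along a fixed `tidal_axis_deg`, superposed on a steady
wind-driven `mean_flow`. Parameter choices:

* `tidal_period_h = 12.42` — the semidiurnal M2 period; its half-cycle gives
  the familiar ~6-h ebb/flood alternation of mid-shelf reefs.
* `tidal_amp = 0.2` m/s with `mean_flow = c(0.02, -0.05)` — peak speeds just
  above 0.2 m/s with a dominant southward drift, matching the strongest
  current regimes of lagoon habitats; users emulating calmer habitats scale
  these down.
* Headings are oceanographic: degrees clockwise from north, direction the
  current flows **toward**, matching current-meter conventions
  (`heading_to_uv()` / `uv_to_heading()`).

Two modifiers add the structure that produces retention:

* `apply_shelter()` multiplies `u,v` inside a polygon by an attenuation in
  `[0, 1]`. Topographic sheltering is represented by its *effect* (weak flow
  in the lee), not by wake dynamics: the effect is what drives retention and
  it can be dialled precisely, whereas a dynamical wake would require a flow
  solver the package deliberately does not contain.
* `add_eddy()` superposes a Rankine vortex — solid-body core of radius `R`
  (default 250 m, i.e. an eddy ~500 m across, the scale observed along reef
  slopes when tidal currents reverse), tangential speed `v_max·r/R` inside,
  `v_max·R/r` outside, truncated at `3R`. Inside the core the velocity field
  is linear in position, so bilinear interpolation reproduces it exactly and
  orbits are a sharp integrator test.

The generators make no claim to dynamical consistency: there is no pressure,
no continuity enforcement, no wave or Langmuir-cell physics. They reproduce
the *statistical structure* the analysis assumes — oscillatory ebb/flood,
shelter zones, eddies, sub-grid instrument noise — which is exactly what is
needed to test the analysis code. Consequently, passing tests demonstrate
correctness of the transport and statistics machinery, not skill of any
particular hydrodynamic model on a real reef.

## Particle tracking

`advect_ensemble()` integrates each particle with classical fourth-order
Runge–Kutta at step `dt` (default 720 s). Substep velocities interpolate the
stored field linearly in time; no dynamics are advanced inside a step. On
50-m cells at 12-min steps this integrator holds orbit radii in a vortex core
to well under 1% per revolution and halving `dt` moves 24-h endpoints by less
than 1% of the path length (both are tested properties).

Semantics that matter for the downstream statistics:

* **Depth binding.** Particles keep their release depth for the whole run; a
  single depth layer drives each scenario. Vertical advection, buoyancy
  change and larval behaviour are out of scope — during the delivery phase
  competent larvae are treated as passive and neutrally buoyant.
* **Release jitter.** Releases are spread uniformly over the release window
  (an hour for delivery scenarios, 19:00–21:00 for spawn slicks), snapped to
  the integration lattice. Jitter can be disabled for deterministic tests.
* **Windage.** When enabled, `wind_drag_pct`/100 of the wind vector is added
  to every particle's velocity. The standard scenario pair is 0% and 3% (the
  3% figure is the convention for surface-floating material). Windage with a
  release depth below 2 m is refused: wind drag is a surface process and the
  delivery depth (3.6 m) deliberately avoids the wind-influenced layer.
* **Open boundary.** A particle that leaves the grid (or enters an
  open-boundary cell) freezes in place with status `boundary_hit`.
  `trim_boundary_artifacts()` then flags all timepoints from one step before
  the first hit onward as excluded for counting, so frozen particles never
  inflate residency counts. With delivery sites a couple of kilometres from
  the boundary this trimming does not alter PRT, because counts cross the
  e-folding threshold long before the plume reaches the boundary (tested).
* **Land.** Steps that would carry a particle onto land are resolved by free
  slip: the along-shore motion component is kept, the onshore component
  dropped, and a particle boxed in on both axes stays put. Particles are
  never beached; artificial beaching would leak particles out of the
  retention statistics.

## Residency: the e-folding particle residence time

The delivery-phase statistic is computed by `filter_stationary()`,
`count_within_radius()` and `efolding_prt()`, swept over sites × days ×
release hours by `prt_survey()` (releases on the hour from 06:00 to 16:00 —
11 per day — and 24-h tracking in the standard survey; 25 sites over 10 days
gives 2750 scenarios).

* **Stationary-artifact filter.** A particle whose position stays within
  `stationary_eps` (1 m) of a fixed point for *strictly longer than* 1 h is
  removed from counting entirely — gridded models can pin particles against
  bathymetry, and a pinned particle would fake retention. Exactly 1 h of
  immobility is retained; the rule is strictly "longer than". Boundary-frozen
  particles are not double-counted by this filter.
* **Counting.** At every 12-min step from release completion, the number of
  retained particles within a 200-m-radius buffer of the delivery source
  (the operational definition used throughout; hourly series are the
  on-the-hour subsamples). `N0` is the post-filter count at release
  completion — with release jitter in moving water it is genuinely below the
  released count, which is why initial concentrations span a range rather
  than equalling the release size.
* **PRT.** The elapsed time at the first step whose count falls below
  `N0 / e` (`efold_threshold_count(3500) = 1288`). The crossing is taken at
  the first discrete sub-threshold step with no interpolation: counts are
  integers on a 12-min lattice and sub-step interpolation would imply false
  precision. Series that never cross within the 24-h horizon are reported
  *as* 24 h with a `censored` flag — censored scenarios are kept, never
  dropped, because retention-frequency summaries need them.
* The "~1 ha" label often attached to such buffers conflicts with the
  explicit 200-m radius (~12.6 ha); the radius is the operational rule here,
  and the label is treated as descriptive only.

Monotonicity is a tested invariant: scaling every current speed by 0.5 never
decreases any scenario's PRT under identical seeds.

## Spawn slicks: allocation and density

The collection-phase workflow seeds buoyant particles at 0.25 m from coral
polygons during the 19:00–21:00 spawn window and tracks them 16 h, with and
without 3% windage. `allocate_release_polygons()` drops polygons under 10%
live coral cover, weighs the rest by `area × cover` (a documented stand-in
for a full cover-to-fecundity workflow; the weight function is pluggable),
and splits each polygon by recursive bisection of its longer axis into
sub-polygons of ~5000 particles each, scaled so the domain totals a
configured particle budget (90 sub-polygons × 5000 ≈ the half-million
particles of a full spawning-night run). `slick_density()` counts
particle-*timepoints* per cell — the sum of per-step rasters — because a slick
is where material lingers, not merely where it passes; cellwise maxima mark
convergence zones.

## Validation

Two independent comparisons mirror field practice:

* **Drifter tracks** (`ensemble_mean_track()`, `track_errors()`): the
  centroid track of 1000 particles released in a 50-m-radius polygon around
  the drifter start is compared hourly — planar separation, signed circular
  difference of trailing-hour displacement bearings (in `(-180°, 180°]`), and
  trailing-hour mean-speed difference; medians summarise a run. Hourly
  displacement bearings (not instantaneous headings) are used because GPS
  fixes at 5–10-min spacing make instantaneous bearings noisy.
* **Benthic current meters** (`hourly_uv_regression()`): both series are
  decomposed to `u,v`, averaged on aligned left-labelled hourly bins
  `[t, t+1h)`, and compared by squared Pearson correlation and RMSE per
  component. RMSE is computed on paired values, **not** regression residuals:
  as a skill metric it must retain constant biases and amplitude errors,
  which residual RMSE would hide.

`categorize_fit()` turns the metrics into the four-way (plus wind-conditional)
fit classification. Because a site can be dominated by one flow axis — an
east–west ebb/flood channel puts all signal in `u`, and a tiny directional
error then wrecks R² of the near-zero `v` — the series are first rotated onto
the observed principal current axis and the rules applied to the dominant
component: `very_good` needs dominant R² > 0.4 *and* dominant RMSE below the
observed dominant-component SD; `good` covers moderate dominant R²
(0.2–0.4), a well-fitting secondary component, or recovery of R² > 0.4 after
a tidal lag correction of at most 2 h; `good_wind` means the `good` criterion
holds only on a wind-direction-conditioned subset of hours; `poor` captures a
coherent tidal signal whose modelled amplitude is off by more than 2× — an
understood but uncorrectable error, which therefore outranks `good` whatever
the raw R² (otherwise added noise could *raise* a category by dragging R²
into the moderate band); everything else is `no_fit`. The `poor` rule also
requires the observations themselves to carry a tidal harmonic (share of
variance > 0.2), so amplitude ratios computed on noise cannot outrank an
honest `no_fit`. All thresholds are arguments; the defaults are the stated
rule set. The "low RMSE" part of the `very_good` rule is quantified here as
RMSE < observed SD — an explicit, testable proxy for what is usually an
expert judgement.

## Slack currents

`segment_speed_series()` is an authored implementation of exact penalized
changepoint detection with PELT pruning on 1-min-averaged speed series. The
default cost is Gaussian mean-shift: residual sum of squares around the
segment mean, normalised by a robust noise variance estimated from lag-1
differences (median absolute deviation based, so level shifts do not inflate
it); a mean-and-variance Gaussian cost is available. The default penalty is
MBIC-style `3·log(n)`; raising it can only reduce the number of changepoints
(tested). Two implementation notes: the pruning uses *delayed exclusion* — a
candidate dominated at time `t` is discarded only from `t + min_segment`
onward, which keeps the search provably exact under a minimum segment length
(the suite checks equality with an exhaustive O(n²) dynamic program on random
series); and the cost normalisation makes the penalty scale-free, so the same
default works for mm/s and m/s records.

`extract_slack_events()` takes segments with mean speed below the 0.022 m/s
slack threshold (the "usually below" of field practice is operationalised as
a hard threshold — reproducibility requires a crisp rule), merges adjacent
qualifying segments, and reports start, end, duration, mean and SD.
`summarize_slack()` aggregates counts and duration ranges per site and pools
a duration histogram; `slack_tide_alignment()` emits event-midpoint versus
tide-time offsets for descriptive plots only — no statistical claim is
attached, since tide timing is known to predict slack conditions poorly on
sheltered reefs.

## Virtual observations

* `sample_drifter()` advects a single 1-m-depth particle with a 60-s internal
  step and samples fixes at 5–10-min intervals with Gaussian GPS noise. GPS
  accuracy is not pinned by any source; `gps_sigma` (default 3 m, typical of
  consumer GPS) is a free parameter of the emulator.
* `sample_tiltmeter()` samples speed/heading from the nearest cell at fixed
  intervals (1 s in field deployments; coarser in tests for speed), then
  applies a sub-grid placement model: meters on exposed reef tops see roughly
  the cell-scale flow (`gain ≈ 1`), meters in grooves between boulders see
  attenuated, directionally scattered flow (`gain < 1`,
  `heading_scatter > 0`). This is the package's abstraction of within-cell
  flow variability — real sub-grid turbulence is not simulated.
* `make_coral_polygons()` packs non-overlapping rectangular reef polygons on
  water with uniform cover draws — a stand-in for mapped habitat polygons;
  real reef outlines are of course not rectangles, which matters only to the
  polygon-splitting geometry, not to any statistic.

All generators are bit-reproducible under a fixed seed, and the pipeline
derives per-scenario sub-seeds deterministically from one master seed so a
single integer reproduces a whole run.

## Problem sizes and runtime

The test-suite and acceptance-script scenarios are sized for thoroughness per
CPU-second, chosen as follows: oracle equivalence uses 10–20 random fixtures
of ≤ 500 samples/particles (enough for the birthday-style collision coverage
that catches indexing errors); the retention-monotonicity sweep uses 25
scenarios of 150 particles (the property is deterministic given seeds, so
particle count only affects count granularity); the end-to-end demo survey
uses 5 sites × 11 release hours × 2 days at 1000 particles on an 80 × 80
grid — large enough that sheltered, open and eddy-edge sites separate cleanly
in PRT, and it completes in a few minutes on one core. Full field-scale runs
(90 polygons × 5000 particles; 2750 delivery scenarios) use the same code
paths and scale linearly in particles × steps.

## Known limitations

* 2-D per-depth-layer transport: buoyant spawn is tracked in a single layer,
  so wind-driven vertical mixing of spawn — a real effect on windy nights —
  is not represented.
* The shelter modifier imposes attenuation rather than emerging from
  dynamics; it cannot produce recirculation, only calm.
* The fit classification is an explicit proxy for what is partly expert
  judgement in field studies; borderline sites can legitimately be argued
  into the neighbouring category by moving the (exposed) thresholds.
* The cover-to-propagule weight (`area × cover`) is the simplest defensible
  choice; any better-calibrated fecundity curve should be supplied via
  `weight_fun`.
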