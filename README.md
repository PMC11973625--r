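# larvaflow

Reef-scale coral larval dispersal simulation and residence-time analysis in R.

## The problem

Larval-based reef restoration needs two operational predictions at the scale
of a single reef system (kilometres, hours): **where** buoyant coral spawn
accumulates after a mass spawning night (so embryos can be collected from
slicks), and **when and where** to release competent larvae so that they stay
over the damaged reef long enough to settle instead of being flushed away.
Both questions reduce to Lagrangian transport of passive particles through
gridded, tidally dominated current fields, plus a handful of summary
statistics: particle-density rasters for convergence zones, the e-folding
particle residence time (PRT) around delivery sites, skill metrics for the
current model against field instruments, and the frequency and duration of
slack-current windows on the reef.

`larvaflow` implements that whole workflow as tested, reusable R functions,
and ships synthetic current/observation generators with the statistical
structure the analysis assumes (semidiurnal ebb/flood tide plus wind-driven
mean flow, topographic shelter zones of attenuated flow, ~500-m Rankine
eddies, GPS drifters fixing every 5–10 min, benthic tilt current meters
sampling at 1 s), so every stage runs end-to-end without any external
hydrodynamic model output.

## The core quantities

* **Advection** — depth-bound particles are integrated with RK4 at a 12-min
  step through bilinearly interpolated `u,v` fields; optional windage adds
  a fixed percentage (typically 3%) of the wind vector for surface slicks.
* **Particle residence time** — for a release of `N0` particles at a site,
  the PRT is the first time the count inside a 200-m buffer drops below
  `N0 / e` (for example, below `⌈3500/e⌉ = 1288` of 3500 released);
  releases that never cross within 24 h are censored at 24 h.
* **Validation** — hourly-averaged modelled vs observed `u,v` compared by
  squared Pearson correlation (R²) and RMSE per component, rotated onto the
  observed principal current axis, then classified into
  `very_good / good / good_wind / poor / no_fit` by an explicit rule set.
* **Slack currents** — 1-min speed series are segmented by exact penalized
  changepoint detection (PELT, Gaussian mean-shift cost); segments with mean
  speed below 0.022 m/s become slack events with start, end, duration,
  mean and SD.

## Worked example

A 3 × 3 km tidal domain with a sheltered retention zone and an eddy; PRT for
two delivery sites, three hourly releases each:

```r
library(larvaflow)

g <- grid_spec(nx = 60, ny = 60, depth_layers = 3.6, time_step = 720, n_steps = 171)
field <- build_tidal_field(g, tidal_amp = 0.12, mean_flow = c(0.01, -0.03))
field <- apply_shelter(field, cbind(c(400, 1800, 1800, 400), c(500, 500, 1900, 1900)),
                       attenuation = 0.08)
field <- add_eddy(field, center = c(2200, 2200), radius = 250, v_max = 0.08)

prt <- prt_survey(field,
                  sites = list(sheltered = c(1100, 1200), open = c(2600, 800)),
                  days = c(day1 = 0), release_hours = 8:10,
                  n_particles = 500, duration_h = 12, seed = 1)
prt
#>        site  day hour  N0 prt_hours censored removed_stationary boundary_trimmed
#> 1 sheltered day1    8 500      24.0     TRUE                  0                0
#> 2 sheltered day1    9 500      24.0     TRUE                  0                0
#> 3 sheltered day1   10 500      24.0     TRUE                  0                0
#> 4      open day1    8 311       0.4    FALSE                  0              500
#> 5      open day1    9 282       0.4    FALSE                  0              500
#> 6      open day1   10 355       0.6    FALSE                  0              500

summarize_prt(prt)
#>        site n max_prt_h median_prt_h n_censored n_ge_5h
#> 1      open 3       0.6          0.4          0       0
#> 2 sheltered 3      24.0         24.0          3       3
```

Reading it: inside the shelter the flow is attenuated to a few mm/s, all 500
particles stay within the 200-m buffer for the whole run and every release is
censored at the 24-h horizon — an ideal delivery site. At the open site the
~0.1 m/s flow sweeps the plume out of the buffer within about half an hour
(the 200 m radius at 0.1 m/s is crossed in ~33 min), `N0` is already below
500 because particles released early in the hour drift off before the release
window closes, and every particle eventually reaches the open boundary
(`boundary_trimmed`), which trims the tail of the counting series without
affecting the PRT.

`demo_run_config()` + `run_pipeline()` run every stage (slick density rasters,
residency, drifter/tiltmeter validation, slack detection) in one call and
write CSV/GeoJSON/ASCII-grid outputs plus a manifest with seeds and checksums.
A thin command-line wrapper lives at `inst/cli/larvaflow.R`.

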