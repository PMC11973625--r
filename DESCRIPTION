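Package: larvaflow
Title: Reef-Scale Larval Dispersal Simulation and Residence-Time Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reef-scale coral larval dispersal analysis on gridded
    current fields: synthetic tidal/wind-driven current generators with
    topographic shelter zones and Rankine eddies, Lagrangian particle tracking
    with optional surface windage, coral-spawn slick density mapping,
    e-folding particle residence time around larval delivery sites,
    model-versus-observation current validation (hourly u/v regression and
    drifter track errors), and changepoint-based slack-current event
    detection. All stages run end-to-end on synthetic fields so no external
    hydrodynamic model output is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ncdf4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
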