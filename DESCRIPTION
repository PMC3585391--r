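Package: schoolstates
Title: Collective States and Transitions in Schooling-Fish Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the collective dynamical states of fish schools
    (swarm, polarized, milling) from per-frame trajectory data. Computes
    polarization and rotation order parameters, segments the smoothed
    order-parameter time series into states and completed transitions,
    measures group geometry (alpha-shape area, packing fraction, distance
    to the tank boundary), builds rotation-polarization phase-space
    density and vector-field maps, and implements a constant-speed zonal
    (repulsion/orientation/attraction) agent-based model with speed-sweep
    experiments. Includes synthetic-data generators for archetypal
    configurations, scripted state-switching series and bounded-tank
    school trajectories so the full pipeline can be exercised without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
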