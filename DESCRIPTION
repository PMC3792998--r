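Package: whaletrack
Title: Switching State-Space Analysis of Satellite-Tracked Whale Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Argos satellite telemetry of large whales
    with a hierarchical two-state switching state-space model. A
    first-difference correlated random walk process model with
    behaviour-specific turn angle and move persistence is coupled to a
    t-distributed observation model indexed by Argos location class, and
    fitted by Markov chain Monte Carlo. Downstream analytics cover
    behavioural classification (transiting, area-restricted search,
    uncertain), track kinematics on the sphere, departure detection and
    residency analysis with right censoring, discrete area-restricted
    search areas with minimum convex polygon sizes, diel activity profiles
    via cyclic harmonic regression, and NOAA-algorithm solar events. A
    synthetic track generator reproduces the two-regime movement process
    with Argos-like heavy-tailed observation error so the whole pipeline
    can be exercised without telemetry data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
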