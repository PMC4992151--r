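Package: entrainr
Title: Jump-Diffusion Modelling of Microparticle Transport in Suspensions of
    Swimming Microalgae
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of the transport of passive micron-sized
    particles in dilute suspensions of swimming microalgae, where rare
    near-contact entrainment events ("jumps") dominate the long-time effective
    diffusivity. Provides a two-dimensional jump-diffusion trajectory simulator
    (Brownian motion alternating with Poisson-initiated ballistic jumps, with
    optional sedimentation drift and reflecting walls), the microscopic
    estimator chain used on particle-tracking data (mean-square displacement
    and diffusivity fits, jump-event detection, jump-length and waiting-time
    statistics with censoring diagnostics, displacement distributions and
    modified kurtosis), a two-state continuum theory with its long-time,
    low-concentration and short-time diffusivity limits and the entrainment
    cross-section, the macroscopic inversions (Perrin sedimentation
    equilibrium, band-spreading fits, Stokes settling speed), and synthetic
    data generators emulating the tracking, sedimentation and band-spreading
    experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
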