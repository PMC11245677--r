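Package: segclock
Title: Delayed-Autorepression Segmentation Clock Models Linking Genome and
    Nuclear Size to Developmental Tempo
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Models the vertebrate somitogenesis segmentation clock as a
    two-variable delayed negative-feedback (Lewis) oscillator and asks how
    genome size and nuclear volume slow its period. Derives species-specific
    kinetic parameters for Xenopus laevis and Ambystoma mexicanum from gene
    structure, nuclear geometry, and clock-period fractions; estimates the
    nuclear mRNA export delay as the mean first-exit time of simulated 3D
    Brownian and fractional Brownian (subdiffusive) trajectories from
    spherical nuclei, calibrated to the empirical zebrafish export time;
    integrates the delay differential equations with a compiled fixed-step
    method-of-steps solver; extracts period, amplitude, and robustness from
    trajectories with an extrema-based protocol; and drives period grids over
    total delay and protein half-life, a +/-50 percent sensitivity analysis,
    and mRNA-stability scaling scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
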