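Package: reachframes
Title: Reference-Frame Analysis of a Desired-Trajectory Model of Reach Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of gain-modulated, Gaussian-tuned units from
    a basis-function network that computes desired reach trajectories in visual
    (eye-centered) coordinates, and applies the standard single-cell analysis
    pipeline to them: center-out tuning screens with a spike-variance-explained
    criterion, a six-parameter reference-frame regression with a continuous
    eye-to-hand weight, stepwise classification by nested F-tests, time-resolved
    reclassification during simulated movement, and gradient (resultant-vector)
    analysis of condition-response matrices with angle doubling. Includes
    alternative network architectures for model comparison and a brute-force
    grid-search reference fitter for validating the bounded least-squares fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
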