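Package: gkverify
Title: Dosimetric Verification of Gamma Knife Convolution Dose Calculations
    in Inhomogeneous Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end verification pipeline for stereotactic radiosurgery
    dose calculations in the presence of bone and air inhomogeneities.
    Generates a voxelized inhomogeneous solid-water sphere phantom with a
    synthetic CT, maps CT numbers to electron and mass densities, computes
    3D dose with a deterministic convolution-style kernel engine and a
    stochastic kernel Monte Carlo engine using sector-based source sampling,
    simulates radiochromic film measurements, converts dose-to-water film
    readings to dose-to-medium, registers film to the stereotactic frame via
    fiducial pins, and compares distributions with a local dose-difference /
    distance-to-agreement gamma index, including GUM-style uncertainty
    budgets and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
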