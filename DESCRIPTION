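Package: nanoscint
Title: Energy Deposition in Hybrid Nanoscintillator Assemblies and
    Radioluminescence Spectral Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of keV X-ray energy deposition in
    porphyrin-functionalized SiO2/ZnO nanoscintillator assemblies, and
    decomposition of radioluminescence spectra into signed Gaussian
    components. Provides approximate photon cross-section and electron
    stopping-power tables for the light elements and zinc, closed-form
    ray tracing for core-satellite and core-shell nanogeometries, analog
    and forced-first-interaction photon/electron transport with
    condensed-history electron stepping, per-medium energy-partition and
    first-interaction-conditioned radial deposition scoring, a
    Levenberg-Marquardt fitter for emission spectra with negative-area
    absorption components at the porphyrin Q-band energies, Beer-Lambert
    dye quantification, and generators for synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
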