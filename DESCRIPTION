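Package: serrsmap
Title: Quantitative Analysis of SERRS Nanoparticle Raman Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hyperspectral Raman maps acquired with
    surface-enhanced resonance Raman scattering (SERRS) nanoparticle contrast
    agents. Provides plain-text readers and writers for point spectra and
    spectral maps, fluorescence-baseline removal by an asymmetrically
    reweighted Whittaker penalized-least-squares smoother with a fast banded
    Cholesky solver, band-intensity quantification of the nanoparticle
    fingerprint (mean counts per second over a wavenumber band), rectangular
    region-of-interest averaging with expression-level classification and
    two-sample t-tests, saturating calibration-curve fitting with
    three-sigma limit-of-detection estimation from dilution series, and a
    deterministic synthetic hyperspectral generator with known ground truth
    for validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
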