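Package: dosekit
Title: Accelerated Voxel-Phantom Monte Carlo X-Ray Dose Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale Monte Carlo photon transport on voxel phantoms for
    interventional X-ray dosimetry. Implements Woodcock delta-tracking with
    a kerma approximation, primary/scatter dose separation and air-kerma
    normalization at the interventional reference point; accelerates
    simulations by statistical-mode down-sampling of the patient model and
    reconstructs high-resolution dose distributions by guided-filter
    super-resolution in the photon-energy-fluence domain. Includes a
    synthetic head phantom generator, embedded tissue
    interaction-coefficient tables, X-ray tube spectra, C-arm beam
    geometry, MHD/NIfTI volume input/output, organ-dose summaries and
    comparison against point dosimeter measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
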