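Package: petmrqa
Title: Quality Assurance Analysis for Simultaneous PET-MR in Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of the six phantom-based quality-assurance
    tests used for radiotherapy-planning PET-MR scanners: ACR-style MR image
    quality metrics, large field-of-view MR geometric distortion, laser and
    couch mechanical accuracy, PET-MR spatial alignment via rigid point-set
    registration, diffusion-weighted MR apparent diffusion coefficient (ADC)
    accuracy against temperature-interpolated references, and PET standard
    uptake value (SUV) accuracy with radioactive decay correction. Includes
    a minimal DICOM series reader/writer, synthetic phantom-image generators
    with known ground truth for end-to-end validation, and a repeatability /
    longitudinal stability statistics and reporting layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    RNifti,
    optparse
Config/testthat/edition: 3
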