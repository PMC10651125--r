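Package: ramanTBI
Title: Raman Spectral Detection of Traumatic Brain Injury via the Retina
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end chemometric pipeline for detecting traumatic brain
    injury (TBI) from Raman spectra of the neuroretina. Provides spectral
    preprocessing (cosmic-ray removal, spline and modified-polynomial
    baseline correction, standard-normal-variate and unit-area
    normalization), a supervised Kohonen self-organizing map classifier
    (SKiNET) with self-optimizing-map discriminant index (SOMDI) feature
    extraction, non-negative least-squares decomposition against a
    brain-lipid component library, and peak-ratio biomarker statistics
    with nonparametric ROC evaluation. Includes a calibrated synthetic
    Raman cohort generator so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
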