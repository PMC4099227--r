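Package: lyticgray
Title: Gray-Level Characterization of Lytic Bone Lesions on Digitized Radiographs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of osteolytic bone lesions on
    digitized skeletal radiographs. Provides region-of-interest (ROI)
    extraction from 12-bit grayscale images, edge-preserving Perona-Malik
    anisotropic diffusion denoising, first-order gray-level histogram
    features (mean, standard deviation and percent coefficient of variation
    of gray level), and nonparametric ROC analysis (tie-corrected
    Mann-Whitney AUC with Hanley-McNeil standard errors) for discriminating
    multiple myeloma from osteolytic metastases, stratified by flat versus
    nonflat bone. Includes a calibrated synthetic-data generator that
    reproduces the statistical structure of the published study groups so
    the full pipeline can be exercised without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'imageIO.R'
    'imaging.R'
    'diffusion.R'
    'features.R'
    'diagnostics.R'
    'synthetic.R'
    'pipeline.R'
    'report.R'
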