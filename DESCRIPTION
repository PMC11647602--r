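Package: secmam
Title: Multi-Attribute Monitoring of AAV Capsids by Multi-Detector
    Size-Exclusion Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reducing multi-detector size-exclusion chromatography
    (SEC) data of adeno-associated virus (AAV) preparations into product
    quality attributes: purity and aggregation from fluorescence traces,
    capsid and genome titer from calibration curves with limits of detection
    and quantitation, full/empty capsid fraction from the A260/A280
    extinction-coefficient model, absolute molar mass and RMS radius from
    slice-wise UV-RI-MALS conjugate analysis, and genome-ejection onset and
    completion from thermal-stress series. Includes a physical forward model
    that simulates multi-detector chromatograms (Beer-Lambert UV, intrinsic
    protein fluorescence, refractive index, and multi-angle static light
    scattering with a sphere form factor) for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chromdata.R'
    'ec_model.R'
    'fe_thermal.R'
    'mals.R'
    'peaks.R'
    'pipeline.R'
    'quant.R'
    'secmam-package.R'
    'synth.R'
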