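Package: pm25risk
Title: Satellite PM2.5 Estimation and Population Exposure Risk Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A seasonal spatial-temporal pipeline for estimating gridded
    fine-particulate (PM2.5) concentrations from multiband satellite-style
    reflectance scenes and assessing population exposure risk. Implements a
    dark-target aerosol optical depth (AOD) retrieval driven by a lookup-table
    radiative-transfer inversion, Angstrom-law wavelength interpolation and
    station collocation for validation, six seasonal AOD-PM2.5 regression
    families with model selection, a relative population exposure risk index
    with six-level classification, and global/local Moran's I with permutation
    inference and LISA cluster mapping. A synthetic-scene generator with known
    ground truth makes every stage testable end to end without satellite
    downloads.
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
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
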