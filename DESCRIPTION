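Package: augCLS
Title: Augmented Classical Least Squares Calibration for Quantitative
    Raman Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative spectral calibration by classical least squares
    (CLS) hardened against component information loss. Spectral channels
    whose intensities correlate poorly with the target analyte are appended
    to the concentration matrix as pseudo-components, absorbing the variance
    of unmodeled species, baseline drift, wavelength shift and detector
    nonlinearity; the augmentation size is chosen from the elbow of a
    leave-one-out RMSECV curve. Includes the comparison baselines (target-only
    CLS, all-analyte CLS, concentration-residual augmented CLS, principal
    component regression, partial least squares), a Venetian-blinds
    cross-validation and ANOVA evaluation protocol, and a seeded synthetic
    Raman reaction-monitoring data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
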