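Package: nirherit
Title: Quantitative-Genetic Analysis of Visible and Near-Infrared Meat Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the genetic and environmental architecture of
    absorbance spectra collected on meat, wavelength by wavelength. Provides
    pedigree validation and the numerator relationship matrix (tabular method
    with inbreeding), a simulator of pedigreed populations with herd and
    slaughter-batch structure and replicate reflectance spectra, spectral
    preprocessing (replicate averaging, Mahalanobis outlier editing,
    minimum-cell filtering, per-wavelength standardization), a univariate
    average-information REML engine for the animal model with random herd and
    batch effects, per-wavelength variance-component scans, and summaries of
    variance proportions and intra-herd/batch heritability by spectral band
    (ultraviolet, visible colors, IR-A, IR-B).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
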