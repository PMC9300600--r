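Package: norse
Title: Normalized Sensitivity Ranking of Body-Composition Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks anthropometric and body-composition biomarkers (BMI, WHR,
    ABSI, RFM and others) by how strongly changes in them predict changes in
    the prevalence of common health conditions. Implements normalized
    sensitivity (NORSE) scoring: biomarker derivation and z-score
    standardization, binned population distribution and condition prevalence
    maps on half-standard-deviation grids with small-cell suppression,
    count-weighted slope estimation of prevalence versus biomarker, 1D and
    2D scoring with NORSE separation, ranking tables, age stratification,
    map visualizations, and a synthetic NHANES-like cohort generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    foreign
Config/testthat/edition: 3
RoxygenNote: 7.3.3
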