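Package: adipomorph
Title: Lipid-Droplet Morphometrics and Batched Screen Statistics for
    Zebrafish Adipose Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies hyperplastic versus hypertrophic adipose morphology
    from segmented lipid-droplet label masks in zebrafish subcutaneous
    adipose tissue. Converts integer-labelled segmentation masks into
    calibrated per-droplet measurements (centroid, area, maximum caliper
    ('Feret') diameter), bins droplets into 200 um anterior-posterior
    strata, fits a penalized-spline smoother of mean droplet diameter
    against log depot area and scores each fish by its residual 'morphology
    value', and provides the statistical framework for multi-experiment
    CRISPR screens: pooled and stratified two-sample Kolmogorov-Smirnov
    tests with Fisher combination, random-intercept mixed models with
    back-transformed percent effects, Benjamini-Hochberg families, hit
    classification, effect sizes and noncentral-t power analysis. A
    robustness suite (variance heterogeneity, heteroscedastic mixed models,
    within-experiment permutation tests, Welch tests, consensus calls), a
    paired high-fat-diet spatial analysis, and a synthetic-data generator
    emulating the assumed data structure are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    mgcv,
    lme4,
    nlme,
    tiff,
    png,
    jsonlite
Suggests:
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
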