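Package: plaquemetry
Title: Planimetric Quantification of Disclosed Dental Plaque on Tooth Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-mouth planimetric plaque measurement from cropped
    tooth-on-black raster images. Classifies pixels of disclosed (red-stained)
    plaque by RGB thresholding, reports the plaque-covered percentage of the
    tooth area (P%), renders calibration overlays, and batch-processes image
    sets. Includes a seeded synthetic scene generator with pixel-level ground
    truth for method validation, the agreement and reproducibility statistics
    used in planimetric method-comparison studies (log-scale Bland-Altman with
    proportional- and systematic-bias tests, ICC(A,1), exact Wilcoxon
    signed-rank, Spearman rank correlation, percentile bootstrap confidence
    intervals for medians, Kolmogorov-Smirnov normality screening), and a study
    pipeline for longitudinal site- and subject-level summaries with
    Bonferroni-adjusted timepoint comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    png,
    jpeg,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
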