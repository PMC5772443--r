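Package: sdmabund
Title: Contrasting Presence-Only Species Distribution Models with
    Plot-Based Abundance Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing presence-only species distribution
    models with spatially interpolated relative-abundance maps built
    from forest-inventory plots. Implements an occurrence-record
    cleaning pipeline (geo-validation, grid-cell deduplication and
    kernel-density spatial-outlier removal), inverse-distance-weighted
    relative-abundance surfaces, a minimal maximum-entropy model with
    linear and quadratic climate features and target-group background
    sampling, convex-hull-plus-buffer range clipping, null-model AUC
    significance testing, and the comparison statistics (binomial GLM,
    Spearman correlation, 90th-percentile quantile regression,
    sensitivity and area of occupancy). Ships a fully synthetic study
    system with known ground truth so every stage can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
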