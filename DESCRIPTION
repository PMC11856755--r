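Package: suitcast
Title: Presence-Background Climatic Suitability Modeling with AICc Tuning
    and Multi-GCM Ensemble Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end ecological niche modeling workbench for
    presence-only species distribution data. Provides a raster data model
    for ESRI ASCII grids, occurrence curation (temporal partition,
    per-cell deduplication, Moran's I spatial thinning), predictor
    screening by Pearson correlation, variance inflation and model
    contribution, a maximum-entropy suitability model with linear,
    quadratic, hinge, product and threshold features and L1
    regularization, AICc-driven tuning over a regularization-multiplier by
    feature-class grid, a multi-metric evaluation panel (omission rates,
    AUC, partial-ROC AUC ratio, TSS, Kappa, continuous Boyce index,
    Jaccard and Sorensen), and multi-GCM climate-scenario ensemble
    projection with binary change-map accounting. A synthetic-world
    generator with known truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
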