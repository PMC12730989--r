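Package: sciconn
Title: Longitudinal Brain Network Analysis for Spinal Cord Injury Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how brain network organization changes after
    spinal cord injury and regenerative therapy. Builds individual structural
    covariance networks from regional gray-matter volumes (effect-size
    weighting of a healthy-period group covariance) and positive-correlation
    Fisher-z functional networks from regional time series; binarizes them
    over a proportional sparsity grid and summarizes global graph metrics
    (efficiency, path length, clustering, small-worldness against
    degree-preserving nulls) with area-under-curve summaries; and fits the
    longitudinal statistical layer: decision-tree group comparisons,
    mixed-effects moderation models with simple slopes and effect sizes, and
    penalized-spline trajectory models. Includes a seeded synthetic-cohort
    generator that emulates the study design, so the full pipeline runs
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    lmerTest,
    mgcv,
    car,
    jsonlite,
    yaml,
    withr,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse
Config/testthat/edition: 3
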