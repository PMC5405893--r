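Package: naplines
Title: Two-Line Nonaccidental-Property Stimuli, Gabor-Jet Audit, and
    Visual-Search Reaction-Time Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for odd-one-out visual-search experiments on two-line
    configurations that isolate nonaccidental properties (collinearity,
    alignment, cotermination, parallelism, junction type, curvature of
    edges and of the configural axis).  Generates parametric
    base/metric/nonaccidental stimulus triplets in degrees of visual
    angle, rasterizes them to grayscale images, audits low-level
    similarity with a V1-like Gabor-jet model compared by cosine
    similarity, builds fully factorial four-quadrant trial tables,
    simulates shifted-lognormal observers with a configurable
    nonaccidental detection advantage, and analyses reaction times with
    per-participant medians, one-tailed paired t tests under Bonferroni
    correction, 2x2 within-subject interaction tests, and
    model-behaviour correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
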