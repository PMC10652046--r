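Package: factorscreen
Title: Factorial Inhibitor-Screen Modelling of Emergent Cell Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for two-level factorial small-molecule inhibitor
    screens of cultured cells. Covers the full path from raw measurements to
    interpretable models: condition coding and one-hot design matrices for a
    2^5 inhibitor design with viability masking, normalisation of colony
    morphology scores, qPCR (delta-delta-Ct) and immunoblot band intensities,
    variance-stabilising transforms with Shapiro-Wilk checks, multiple linear
    regression with all pairwise interaction terms and nested F-tests,
    classification of inhibitor pairs as additive, synergistic or
    antagonistic, a Bayesian-regularised feed-forward neural network trained
    by evidence maximisation with effective-parameter-adjusted fit statistics,
    and exploratory structure discovery (correlation matrices, z-scored PCA,
    silhouette-guided k-means). A synthetic-data generator with planted ground
    truth makes every stage testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
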