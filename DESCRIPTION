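Package: shapescreen
Title: Shape-Based Scoring of Single-Cell-Resolved Perturbation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects perturbations in high-content screens as changes in the
    shape of per-well single-cell phenotype distributions. Wells are
    normalized to zero mean and unit variance so that affine (background and
    scale) imaging artifacts cancel, compared with a scaled two-sample
    Kolmogorov-Smirnov statistic anchored to negative-control wells, and
    summarized as per-slide Z-scores. Hits are called from triplicate
    Z-scores with a 2-of-3 rule against a permutation null band; a
    binomial-mixture model of triplicate bin counts infers the screen's hit
    fraction, false-positive rate and the distribution of per-gene
    true-positive rates. Includes plate-artifact diagnostics (moment ANOVA,
    nonlinear-rescale checks, neighbor-based partial normalization), a
    classifier/output cell-state analysis, and a synthetic screen simulator
    with controlled affine artifacts and gene-specific penetrance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
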