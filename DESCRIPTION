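Package: psynetcomp
Title: Comparing the Correlation Architecture of Psychopathology Between
    Clinical Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing inter-scale correlation networks of
    psychopathology between two clinical groups, each standardized against
    its own matched control group. Builds per-group Pearson correlation
    networks over questionnaire scales, Fisher-Z transforms them, and
    compares groups at four levels: nodal degree (with Deming orthogonal
    regression against the identity line), connectivity fingerprints
    (divergence = 1 - correlation of matrix rows), the full edge-weight
    distribution (mean difference, Kolmogorov-Smirnov distance, kurtosis),
    and coordinated edge-set differences found by clustering the
    between-group delta matrix with a Gaussian weighted stochastic block
    model selected by the integrated classification likelihood. Inference
    throughout is by group-label permutation. A synthetic-cohort generator
    with a cluster-structured factor model supports calibration and power
    analysis without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
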