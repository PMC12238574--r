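Package: noiseplast
Title: Noise and Plasticity Quantification for Single-Cell Protein Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies stochastic gene-expression noise and phenotypic
    plasticity from single-cell flow-cytometry measurements of fluorescent
    protein fusion strains. Implements cumulative-population FSC gating,
    autofluorescence background correction, population statistics (E_pop,
    V_pop) on the log10 scale, mean-compensated noise via running-median
    plus smoothing-spline residuals (DM_V), across-condition plasticity,
    association analyses (rank correlations, rank-sum and Kruskal-Wallis
    tests, Brown-Forsythe variance comparison, cumulative rank-scan curves,
    PCA with missingness filtering), a growth-threshold conditional
    essentiality classifier for microplate OD595 assays, and a synthetic
    flow-cytometry event generator with planted noise-plasticity coupling
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
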