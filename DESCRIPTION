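Package: spinescreen
Title: Dendritic Spine Morphometry and Phenotypic Compound Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric four-class classification of dendritic spines
    (mushroom, thin, stubby, filopodium) from per-spine length, head and
    neck diameters; neuron-level maturity calling; plate-based two-stage
    phenotypic compound screening against duplicate DMSO vehicle wells
    with dilution-series confirmation and per-target hit-rate tabulation;
    a calibrated synthetic-data generator for neurons, screening plates,
    behavioral cohorts and mEPSC-style samples; and the accompanying
    nonparametric statistics (Mann-Whitney U, Kruskal-Wallis with Dunn's
    post hoc, empirical cumulative distributions, sociability scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
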