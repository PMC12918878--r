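Package: tnseascape
Title: Longitudinal RB-TnSeq Selection Rates and Fitness Seascapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-resolved fitness analysis of pooled, randomly
    barcoded transposon (RB-TnSeq) libraries sampled over an extended
    bacterial growth curve. Starting from poolcount-style barcode count
    tables, the package filters low-abundance barcodes, corrects positional
    sequencing bias with a sliding median, normalizes counts by a centered
    log-ratio transform against an empirically neutral gene set, and derives
    per-barcode interval selection rates. Gene-level selection rates for each
    sampling interval are then inferred with a hierarchical Bayesian
    multilevel model (correlated gene effects with an LKJ prior, Student-t
    hyperpriors, Gibbs-within-Metropolis sampling) that returns full
    posterior distributions, net selection rates, and probabilistic
    beneficial/deleterious classifications. A benchmarking simulator with
    explicit intragenic, measurement, and batch noise channels evaluates the
    model against a BarSeq-style t-interval baseline by RMSE and coverage
    probability. A one-dimensional Fisher's geometric "seascape" model
    places mutants on a latent phenotypic axis with one quadratic fitness
    landscape per interval, linked through a discretized Ornstein-Uhlenbeck
    prior on the moving optimum. Downstream utilities cover trajectory PCA
    and k-means clustering, regulon signed-sum predictions, and
    permutation-null enrichment tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
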