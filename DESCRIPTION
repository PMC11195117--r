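Package: boutonpipe
Title: Analysis of Axonal Bouton Activity and Structural Dynamics from
    Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for longitudinal two-photon imaging of axonal
    boutons in behaving mice performing a cued lever-pushing task. Detects
    lever-movement bouts and labels them as rewarded (RM) or un-rewarded
    (UM); computes dF/F with a sliding-percentile baseline and detects
    calcium events with a dual z-score/amplitude criterion; classifies
    boutons and axons by reward-outcome selectivity; embeds trial-averaged
    activity with PCA and quantifies single-trial trajectory selectivity;
    measures same-axon bouton activity heterogeneity by inter-bouton peak
    matching; and quantifies structural bouton turnover (formation,
    elimination, survival, density, spatial clustering of new boutons).
    Ships a synthetic-data generator with full ground truth so every stage
    is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
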