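Package: phylopred
Title: Phylogeny-Based Prediction of Continuous Traits in Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying phylogenetic signal in continuous traits of
    community members (Blomberg's K with a permutation test), estimating
    ancestral trait values under Brownian motion by generalized least squares,
    predicting traits of unobserved tips by tree pruning and rerooting, scoring
    prediction accuracy by replicated tip-exclusion validation, and transferring
    predictions across communities through ancestral nodes shared between their
    pruned phylogenies. Includes a synthetic-data generator (Yule trees,
    Brownian trait evolution, overlapping community subsets with a tunable
    heritable fraction) so the whole workflow can be exercised and calibrated
    without external data, and a configuration-driven pipeline that emits
    tabular summaries of signal, within-community validation and cross-community
    prediction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    phytools,
    jsonlite
Config/testthat/edition: 3
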