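Package: deltaC1
Title: Early Retinotopic Visual ERP Suppression and Race-Model Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying crossmodal influences on the earliest retinotopic
    visual cortical response and on audiovisual reaction-time gains. Implements an
    epoch-based ERP pipeline for the C1 difference wave (lower minus upper visual
    field, 50-100 ms) including zero-phase filtering, ocular and motor artifact
    rejection, nasion-inion electrode mirroring and baseline correction; Bayesian
    hierarchical cell-means and contrast models with directional Savage-Dickey
    Bayes factors, highest-density intervals and ROPE decisions; behavioral
    analyses of the redundant-target effect including the race model inequality
    violation area, a cluster-based sign-flip permutation test with
    Benjamini-Hochberg correction, and an exponential-null Bayesian test; and a
    synthetic EEG and reaction-time generator with known ground truth for
    validating every stage.
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
    coda,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
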