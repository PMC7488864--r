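Package: annoqc
Title: Quality Auditing of Multi-Rater Annotation Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the quality of multi-rater categorical annotation datasets
    ("Diamond Standards") used to train supervised models. Measures reliability
    of the raw annotations through confidence-based chance-discounted agreement
    (degree of concordance and degree of weighted concordance, with
    intra-rater-variability intervals), estimates the accuracy of reduced
    reference labels ("Gold Standards") through the degree of fineness under
    majority, probabilistic, confidence-weighted and accuracy-weighted
    reductions (exact Poisson-binomial model, Chernoff bound, and a rater-count
    planner), and measures representativeness between feature datasets through
    the degree of correspondence, a bootstrap p-value built on minimum-cost
    matching and substitution of pairwise-distance distributions. Includes an
    evidence-theoretic derivation of the concordance metrics (simple mass
    functions with Dempster, Dubois-Prade and mixing combination rules), a
    seeded synthetic annotation and feature simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    MASS,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    clue,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
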