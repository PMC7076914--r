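Package: inducenet
Title: Causal Gene Regulatory Network Inference from Transcription
    Factor Induction Timecourses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for learning causal gene regulatory networks from
    timecourses of genome-wide expression following rapid induction of
    single transcription factors. Covers the full analysis chain: a
    simulator of ground-truth networks and induction experiments down to
    two-channel spot intensities; cleaning of raw spot data (spot
    aggregation with intensity floors, outlier and channel-crosstalk
    repair, induction-system signature subtraction, and noise-model
    hard-thresholding); penalized maximum a posteriori fitting of
    sigmoid and impulse (double-sigmoid) kinetic models with
    likelihood-ratio model selection; per-gene sparse dynamical
    regression with L1 regularization and BIC or held-out-experiment
    cross-validation; marginal attribution of expression responses to
    individual regulators; and synthesis plus ROC benchmarking of the
    resulting causal graphs against reference networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
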