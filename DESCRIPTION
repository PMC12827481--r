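Package: aegisr
Title: Transcriptomic Risk Scoring of Drug-Induced Liver Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a dose-dependent drug-induced liver injury (DILI)
    risk score from treatment-versus-control transcriptomics by testing
    the perturbation of apoptosis-regulating transcription-factor
    regulons. Provides per-gene linear modelling with empirical-Bayes
    variance moderation, a self-contained rotation gene-set test with
    floormean summary statistics, score normalisation with
    noise-injection confidence estimates, stepwise threshold calibration
    with classification metrics, exact tests for compound panels,
    log-logistic dose-response fitting, a synthetic-experiment generator
    for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
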