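Package: TransMark
Title: Translational Blood Biomarker Triage and Cross-Species Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested workflow for triaging blood-borne transcript biomarkers
    of chronic neuropathic back pain and validating them across species.
    Implements a two-group differential-expression screen with a
    multi-criteria refinement gate, pairwise-complete gene-gene correlation
    over heterogeneous two-colour microarray compendia with planted-module
    detection, qPCR relative quantification with multi-reference
    normalization and geNorm stability, digital droplet PCR Poisson copy
    estimation, ELISA four-parameter-logistic standard curves with
    nonparametric plasma statistics, and an end-to-end pipeline producing a
    cross-species concordance report. Every input can be simulated by
    calibrated synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    minpack.lm,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
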