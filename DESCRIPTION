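Package: httrpod
Title: Transcriptomic Points of Departure and Potency Ranking for
    High-Throughput Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for concentration-response
    high-throughput transcriptomics (TempO-Seq-like) count data: study-wide
    sample quality control (Spearman distance, read-depth, probe-coverage
    fences, Gini coefficient), per-concentration differential contrasts
    against plate-matched solvent controls with R-ODAF count filters,
    directional gene-signature scoring (running-Fisher rank scan) for
    estrogen receptor alpha and cellular stress biomarkers, cytotoxic-burst
    flagging, per-gene benchmark concentration (BMC) modeling with a
    Williams trend prefilter, a seven-model fitting suite with AIC
    selection and profile-likelihood bounds, and derivation of three
    transcriptomic points of departure (25th rank-ordered gene BMC, lowest
    pathway-median BMC, biomarker-median BMC with parametric-bootstrap
    confidence intervals) for cross-chemical potency ranking. Includes a
    negative-binomial synthetic-data generator with analytic ground-truth
    BMCs and injectable QC failures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
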