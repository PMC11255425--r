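Package: fscv
Title: Multichannel Fast-Scan Cyclic Voltammetry Dopamine Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for chronic 16-channel fast-scan cyclic
    voltammetry (FSCV) recordings of stimulated dopamine release: a raw
    binary voltammogram dialect with JSON sidecar metadata, per-scan
    low-pass and across-time zero-phase high-pass Butterworth filtering,
    principal component regression chemometrics with residual (Q)
    screening, flow-cell calibration curves, cross-channel outlier QC,
    stimulated-release (ES DA) and clearance time-constant (Tau)
    quantification, and the repeated-measures/mixed-model statistical
    layer used for group comparisons across weekly sessions. Includes a
    seed-deterministic synthetic recording generator with ground truth so
    every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
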