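Package: ssvepr
Title: SSVEP Frequency Recognition with CCA, LASSO and Robust Nonlinear CCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Frequency recognition for steady-state visual evoked potential
    (SSVEP) brain-computer interfaces. Implements three detectors over
    multichannel EEG epochs: canonical correlation analysis against sinusoidal
    harmonic references, sparse (LASSO) regression with per-frequency
    contribution scoring, and a robust nonlinear CCA built from double-barreled
    tanh networks trained with the biweight midcorrelation and mean-absolute-
    error inverse-mapping costs. Includes a synthetic SSVEP generator
    (steady-state harmonics, transient N75/P100/N135 stage, 1/f background
    noise, channel mixing), zero-phase bandpass preprocessing, fixed and
    sliding window extraction, and an evaluation layer: accuracy, Wolpaw
    bits/trial and information transfer rate, coefficient of variation,
    sliding-window phase-effect experiments, one-way ANOVA and Tukey critical
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
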