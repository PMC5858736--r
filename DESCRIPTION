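Package: scanseq
Title: Sequential Context Effects in Image Reader Studies via Scanpath
    Fractal Dimension
Version: 0.1.0
Authors@R:
    person("scanseq", "developers", email = "scanseq@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and quantifying sequential context effects
    in diagnostic image reading studies. Quantifies visual search behavior by
    the Minkowski-Bouligand box-counting fractal dimension of gaze scanpaths,
    builds lag-structured datasets pairing current diagnostic decisions with
    prior behavior, decisions and case properties while honoring session
    boundaries, and tests and predicts sequential dependence via
    autocorrelation functions with significance bands, multifactor
    fixed-effects ANOVA with partial F tests, and per-reader
    leave-one-case-out random-forest classification scored by weighted
    f-score against a random-chance baseline. Includes a synthetic
    reader-study generator with injectable context bias for end-to-end
    calibration and recovery experiments, plus tabular gaze I/O and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
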