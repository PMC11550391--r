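Package: hrsysid
Title: System Identification of Heart-Rate Dynamics During Exercise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying continuous-time dynamic models of the
    heart-rate response to exercise intensity from paired treadmill or
    cycle-ergometer tests. Implements a family of seven process-model
    structures with up to two poles, a zero and a dead time (including a
    parallel two-branch form capturing fast delayed response plus slow
    drift), exact zero-order-hold simulation with fractional dead time,
    bounded multi-start least-squares parameter estimation, a normalised
    root-mean-square (NRMSE) fit metric, counterbalanced cross-validation
    over replicate test pairs, and a structure-comparison pipeline. A
    synthetic-data module generates pseudo-random binary sequence (PRBS)
    excitations and paired synthetic records so the full analysis is
    testable without access to human datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
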