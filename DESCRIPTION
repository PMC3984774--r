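Package: GRNcomplete
Title: Completion and Inference of Gene Regulatory Networks from Steady-State Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Completes and infers directed gene regulatory networks from static
    (steady-state) expression data. Each gene's stationary expression level is
    modelled as a quadratic polynomial in the expression of its regulators,
    fitted by least squares; a dynamic program over per-gene edge-addition and
    edge-deletion budgets finds the network modification with minimum total
    residual error, with per-gene caps keeping the enumeration polynomial.
    Starting from an empty network the same machinery performs network
    inference. Includes a generator for synthetic quadratic fixed-point
    equation systems with enumerable exact solutions and an induced
    gold-standard network, accuracy metrics for completion and inference, a
    benchmark harness, and TSV/SIF readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
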