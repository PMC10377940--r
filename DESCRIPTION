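Package: pidchannels
Title: Partial Information Decomposition via Channel Preorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes intersection-information (redundancy) measures for the
    partial information decomposition (PID) of finite discrete systems.  A
    redundancy measure is obtained by maximizing I(Q;T) over all variables Q
    that sit below every source under a chosen preorder between channels:
    degradation (Blackwell), less-noisy, more-capable, and
    degradation/supermodularity.  The package provides decision procedures
    with certificates for these channel orders, the minimum-mutual-information
    and deterministic (Gacs-Korner) reference measures, bivariate
    decompositions into redundant, unique and synergistic components,
    deterministic fixtures for the classic logic-gate examples, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
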