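Package: broilerDEA
Title: Data Envelopment Analysis for Broiler Production Benchmarking
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Relative-efficiency analysis of integrated broiler production
    units with Data Envelopment Analysis (DEA). Solves the CCR (constant
    returns) and BCC (variable returns) envelopment models in input and
    output orientation by two-phase simplex, computes inverted-frontier and
    composite efficiency rankings, derives the standard zootechnical
    indicator panel (viability, daily weight gain, feed conversion ratio,
    production efficiency factor), and ships a 31-batch reference dataset
    from a Brazilian integrated production system together with simulators
    for realistic farm tables and planted-efficiency frontiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    boot,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
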