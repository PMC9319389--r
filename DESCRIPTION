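Package: relw
Title: Relative-Weight Diagnostic Scoring and Exhaustive Explanation Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretable additive scoring for binary diagnostic variables
    (patient symptoms or medical-image findings). From a counting dataset --
    the number of patients exhibiting each variable in a cohort -- the package
    computes per-variable relative weights by normalizing counts to sum to one,
    scores any presence/absence profile into a positive likelihood value
    (the sum of present variables' weights) and its complement, and
    stream-enumerates the full table of all 2^k profiles with their scores.
    Includes validated CSV/TSV/JSON dataset input and output, pre-tabulated
    (supplied) weight tables with normalization diagnostics, ranked
    per-variable explanation reports, a seeded synthetic-data generator for
    property testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
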