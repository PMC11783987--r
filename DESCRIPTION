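Package: recallseq
Title: Start- and End-Sequence Scoring for Immediate Recall Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scoring and analysis of immediate serial recall (ISR) and
    immediate free recall (IFR) output protocols. Detects start-sequences
    (runs of recalls from consecutive input positions beginning with the
    first list item) and end-sequences (runs terminating with the last list
    item), computes serial-position curves under serial, free, and
    sequence-based scoring rules, residual "Other"-item curves, observed
    transposition matrices and error-only transposition gradients, and a
    "start + guess + end" permutation null model in which items outside the
    detected sequences carry no positional information. Includes a synthetic
    recall-protocol generator with controllable sequence-length
    distributions and noise rates, exact replay of published start/end
    cross-tabulations, and tidy CSV/JSON reporting commands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
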