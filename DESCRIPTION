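Package: dishtools
Title: Liver Safety Screening Graphics for Trials with Abnormal Baseline Liver Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening toolkit for drug-induced liver injury (DILI) signals in
    clinical trials whose subjects may have abnormal baseline liver tests.
    Derives per-subject baseline and on-treatment peak ALT/AST/TB values in
    multiples of the upper limit of normal (xULN) and of each subject's own
    baseline (xBL), assigns eDISH quadrant categories (NNN, Cholestasis,
    Temple, Hy's Law), classifies baseline-to-peak category shifts, and builds
    the companion screening artifacts: Sankey shift diagrams with
    cross-tables, composite per-destination mDISH plots, modified waterfall
    plots of baseline-anchored ALT change, classical eDISH scatterplots, a
    tool-applicability advisor, and a deterministic synthetic-trial simulator
    so the whole pipeline is testable without patient data.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
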