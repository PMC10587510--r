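Package: hookahrisk
Title: Elemental Mass Balance and Health Risk Assessment for Hookah Tobacco
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for multi-element (ICP-MS style) concentration
    panels measured on waterpipe (hookah) tobacco and its combustion
    compartments. Parses left-censored ("<LOD") concentration tables, applies
    censoring-substitution policies, computes main-element composition shares,
    partitions each element's per-session burden across ash, bowl water and
    (by difference) inhaled smoke, derives chronic daily intake, hazard
    quotients and lifetime cancer risk with negligible/tolerable/high
    classification, and compares tobacco types with a Friedman rank test
    implemented from first principles (mid-ranks, tie correction, exact
    permutation p-values on small designs). A seeded synthetic-study
    generator with known ground-truth transfer fractions makes every stage
    testable end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
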