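Package: sindex
Title: Combined Potency-Effectiveness Scoring for High-Throughput Drug Screens
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores quantitative high-throughput drug screens by combining
    curve effectiveness (EFF, the span between the zero- and
    infinite-concentration asymptotes of a four-parameter logistic fit) and
    potency (AC50) into a single index S = log10(EFF/AC50). Differences of S
    between a reference and a test cell line (delta-S) classify compounds as
    sensitising or resistance-associated, aggregate to per-compound delta-S
    means with variance-based prioritization filters, and are compared against
    potency-only (delta-pAC50) and area-under-curve (delta-pAUC) rankings.
    Includes a bounded multi-start 4PL fitter, readers and writers for raw and
    pre-fitted screen-table dialects, a synthetic-screen generator with known
    ground truth, plotting helpers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
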