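Package: circadiff
Title: Differential Circadian Rhythmicity Analysis with Cosinor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting and comparing circadian rhythms in
    time-course gene expression and wearable-device data between two
    groups. Implements fixed-period single-component cosinor estimation
    (MESOR, amplitude, peak hour), a joint two-group cosinor model with
    Wald tests for differences in MESOR, amplitude and phase, four-model
    rhythmicity classification by normalized BIC (Schwarz) weights, gene
    categorization with fold-change filters, a three-round heatmap
    normalization, a two-sample bootstrap Kuiper test for circular phase
    comparisons, and a synthetic-data generator emulating a two-group
    serum-synchronization time-course design for validation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
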