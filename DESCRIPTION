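Package: wormscreen
Title: Hit Calling for Reproductive-Fitness RNAi Screens in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 96-well liquid-culture RNAi screens that
    score worm viability as reproductive fitness (progeny per parent). Covers
    reading and writing plate-structured screen tables, the parent-count
    quality window, per-plate sample-median normalization, technical-replicate
    summarization, mutant/wild-type fitness ratios, threshold-based
    enhancer/suppressor classification, control-calibrated cut-off selection
    from predicted false-positive/false-negative rates, and final hit calling
    by agreement across biological replicates. Includes a negative-binomial
    screen simulator with planted synthetic-lethal effects for end-to-end
    validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
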