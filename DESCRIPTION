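Package: tloxr
Title: Proliferative History Tracking with Tandem-loxP Sister-Chromatid
    Recombination Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models Cre-mediated sister-chromatid recombination at tandem
    loxP (Tlox) reporter cassettes and the cumulative labeling it produces in
    proliferating cell populations. Provides exact crossover combinatorics on
    tandem loxP arrays, analytic and stochastic (branching-process) labeling
    curves gated by Cre-expression windows, a stage-structured model of B- and
    T-lymphocyte development, a BrdU pulse-labeling comparator, statistical
    inference of proliferative history from labeled-cell fractions with
    mouse-level resampling, and a synthetic flow-cytometry cohort generator
    for end-to-end testing of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
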