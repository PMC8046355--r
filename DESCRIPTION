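Package: y2hngis
Title: Scoring and Simulation of Yeast Two-Hybrid Deep-Sequencing Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate bait-prey protein-protein interactions from
    next-generation yeast two-hybrid interaction screens (Y2H-NGIS). Prey read
    counts are modelled with gene-wise negative binomial Wald contrasts of
    selected against non-selected cultures (enrichment) and against other
    selected baits (specificity); in-frame fusion-read proportions are tested
    with a pooled two-proportion z statistic. The three resulting rank-based
    scores and their Borda ensemble lie in [0, 1]. A Galton-Watson
    branching-process simulator generates labelled synthetic screens (library
    sampling, selective growth, negative binomial sequencing noise, binomial
    fusion reads) so the scores can be validated with ROC and precision-recall
    curves against known truth. Includes library-size, TPM, median-of-ratios
    and replicate-based RUV normalization with replicate-variability
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
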