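Package: limbnet
Title: Gene-Network Models and Expression-Variation Statistics for Mammalian Limb Development
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of the early (ESN) and late
    (LSN) stage gene regulatory networks governing mouse limb outgrowth, with
    in-silico link-removal and parameter-sensitivity robustness screens;
    coefficient-of-variation statistics for among-individual expression
    variation with Bartlett, litter-ANOVA and Monte-Carlo shuffle tests;
    cross-species expression-conservation scoring (mean pairwise Spearman)
    with gene-set subsampling; and a bootstrap correlation linking
    within-population variation to between-species divergence. Includes a
    synthetic-data generator emulating staged qPCR expression tables and
    ortholog expression matrices so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
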