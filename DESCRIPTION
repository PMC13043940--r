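Package: pairdiv
Title: Demographic Inference from Pairwise Sequence Differences in Short Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting and hierarchical selection of four
    two-population divergence models (strict isolation, isolation with
    migration, isolation with initial migration, and a secondary-contact
    admixture pulse) to the distribution of pairwise sequence differences in
    short, putatively neutral blocks sampled one haplotype per species.
    Includes binomial phasing of heterozygous sites into per-block
    S-distributions, likelihood-ratio model selection with chi-square
    thresholds, conversion of scaled estimates to natural units via a
    mutation-rate model, coalescent simulators for all four models (including
    an ancestral-recombination simulator for the strict-isolation null), a
    false-positive power analysis, and comparative statistics contrasting
    sympatric and allopatric species pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
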