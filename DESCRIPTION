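Package: bowtievar
Title: Abundance Variability, Conservation and Bow-Tie Layers of Human Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating cross-cell-line protein abundance, abundance
    variability and phylogenetic conservation to the functional organization of
    human signaling pathways. Implements an ANOVA-style F-value variability
    statistic on replicated proteomics intensity matrices, a weighted
    species-tree (pruned-subtree) conservation score, bow-tie layer pooling of
    pathway annotations with rank-based feature comparisons, resampling of
    interacting and non-interacting protein pairs with permutation nulls, and
    binned somatic/germline/SNP mutation profiles, together with a seeded
    synthetic-data generator that plants all of these effects for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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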