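Package: pureR
Title: Predicting Upstream Regulators from Differential Expression and
    Chemical-Gene Interaction Knowledge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements PURE, a causal-analysis method that infers which
    chemical, drug, or toxicant (CDT) is elevated or lacking in a phenotype
    from its differential-expression profile and a signed chemical-gene
    interaction knowledge base (CTD-style). For every CDT two directional
    hypotheses are tested with an edge-level one-sided Fisher exact test:
    the CDT is present/overabundant (H1) or deficient/absent (H2).
    Also provides reference implementations of five comparator methods
    (hypergeometric over-representation, Kolmogorov-Smirnov, Wilcoxon
    rank-sum, permutation preranked GSEA, and an IPA-style activation
    z-score with overlap p-value), benchmarking utilities (rank of the
    true CDT, false-positive counts, rank imputation, cross-method
    Wilcoxon comparisons), and a synthetic-data generator for recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
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
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
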