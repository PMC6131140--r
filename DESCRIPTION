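Package: meningiomics
Title: Integrated Transcriptome, Methylation and Copy-Number Subtyping of
    Anaplastic Meningioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproducible pipeline for discovering prognostic molecular
    subgroups in anaplastic meningioma cohorts. Implements Poisson-deviance
    sample clustering with silhouette-based cluster-number selection,
    negative-binomial Wald differential expression with control-gene and
    hidden unwanted-variation factors, minimal marker-panel selection from
    principal-component loadings, Kaplan-Meier and Mantel-Haenszel survival
    comparison, EPIC-style methylation probe filtering and supervised
    delta-beta selection, ploidy-adjusted aggregate copy-number profiling
    with rule-based driver calling, mutational-signature extraction by
    Kullback-Leibler non-negative matrix factorization, and hypergeometric /
    functional-class-scoring enrichment. Ships a multi-omic synthetic cohort
    generator with full ground truth so every stage is testable without
    controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    fgsea,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
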