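Package: pathbench
Title: Gold-Standard-Free Benchmarking of Pathway Analysis Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates pathway analysis methods without a gold standard by
    two complementary resampling metrics: recall (consistency of the top-K
    pathways recovered from random sub-datasets of a large two-cohort
    expression dataset) and discrimination (the fraction of sub-datasets
    correctly associated with their parent dataset rather than a dataset
    from a different condition). Implements six method variants --
    over-representation analysis (ORA), gene set analysis (GSA, maxmean
    with restandardization), gene set enrichment analysis (GSEA) and
    aggregate fold change (AFC), the latter two with gene-label or
    sample-label permutation nulls -- plus a synthetic two-cohort
    expression generator with controlled pathway-level perturbation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
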