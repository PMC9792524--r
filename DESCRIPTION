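Package: noaexome
Title: Recessive-Variant Prioritization and Genetic-Architecture Modelling
    for Non-Obstructive Azoospermia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exome-based gene discovery in non-obstructive
    azoospermia (NOA) and similar rare recessive diseases. Implements a
    recessive-variant prioritization cascade (genotype p-value, allele
    frequency, genotype-recurrence and gene-enrichment filters followed by
    inheritance-mode-aware aggregation criteria and case/control gene
    subtraction), Monte Carlo estimation of the monogenic gene-pool size
    from the rate of recurrent gene hits with false-discovery adjustment
    and cohort-size projections, exact carrier-burden testing with a
    two-stage multiple-testing threshold, tissue-specificity
    classification and single-cell component profile statistics
    (Pearson-Filon tests of dependent correlations, hypergeometric
    enrichment), piRNA length-distribution maturity statistics, and
    consanguinity classification from runs-of-homozygosity length
    mixtures (FROH). A synthetic-data module generates every input with
    planted ground truth so the full pipeline is testable without access
    to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    mclust,
    MASS,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
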