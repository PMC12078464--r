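Package: sesherit
Title: Genetic and Environmental Variance Decomposition of Socioeconomic Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for comparing family-based and
    SNP-based heritability methods on correlated socioeconomic indicators
    (educational attainment, occupational prestige, income, wealth). Includes a
    pedigree, genotype and multi-trait phenotype simulator with known
    additive-genetic (A), shared-environment (C) and non-shared (E) structure;
    maximum-likelihood ACE/AE variance-component models on relative pairs with
    a free or fixed cousin shared-environment correlation; an
    identity-by-descent sibling AE model using KING-robust genome sharing;
    GREML with genomic relatedness matrices; LD-score regression from GWAS
    summary statistics; bivariate component-correlation models; and principal
    component analysis of component correlation matrices with Horn's parallel
    analysis, permutation tests and bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
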