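Package: deltag
Title: Tag-SNP Imputation of the KLRC2/NKG2C 16-kb Deletion Genotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes the three-state KLRC2/NKG2C 16-kb deletion genotype
    (wt/wt, wt/del, del/del) from SNP genotyping data. Scans a genomic
    region for SNPs in linkage disequilibrium with the deletion, ranks
    candidates by random-forest permutation importance, reduces the
    classifier to a minimal tag-SNP panel selected by misclassification
    count and Cohen's kappa, and applies the panel to impute genotypes in
    cohorts typed only on arrays. Also provides the population-genetic
    statistics used to validate and apply such a panel: a Hardy-Weinberg
    likelihood-ratio test, allele-frequency comparisons between
    populations via allele-level logistic regression, multivariable
    case-control logistic association with covariates, and a Monte-Carlo
    power calculator under an additive model. A synthetic-cohort
    generator with controlled deletion-tag linkage disequilibrium serves
    as the test bed.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
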