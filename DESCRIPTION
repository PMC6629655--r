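Package: candgene
Title: Candidate-Gene Case-Control Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for candidate-gene case-control
    association studies of biallelic SNPs: genotype/phenotype file handling,
    Hardy-Weinberg equilibrium testing, allelic and genotypic odds ratios with
    Woolf confidence intervals and Bonferroni correction, covariate-adjusted
    and stratified logistic models, EM estimation of haplotype frequencies
    with D'/r-squared linkage disequilibrium statistics and haplotype
    association, weighted genetic risk scores with Mann-Whitney, logistic and
    ROC/Youden evaluation, and multifactor dimensionality reduction (MDR)
    interaction search with cross-validation and permutation testing. Includes
    a seeded synthetic-cohort generator emulating a nine-SNP TNFAIP3/TNIP1
    ankylosing spondylitis panel so the full pipeline is testable without
    access to individual-level data.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
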