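Package: marsbif
Title: Case-Control SNP Association via MARS and Bootstrap Inclusion Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-step case-control single nucleotide polymorphism (SNP)
    association pipeline for candidate-gene studies: per-SNP inheritance-model
    selection (dominant, recessive, additive) with Benjamini-Hochberg
    correction; linkage-disequilibrium-aware interaction discovery with
    Multivariate Adaptive Regression Splines (MARS, least-squares forward
    search with GCV backward pruning); logistic-regression significance
    filtering of the proposed covariates; Bootstrap Inclusion Fraction (BIF)
    stability validation; and odds-ratio effect estimation with Woolf
    confidence intervals, including competition-level subgroup contrasts.
    Ships Hardy-Weinberg and EM-based r-squared linkage-disequilibrium
    utilities, a genotype-cohort simulator with configurable haplotype-level
    LD and logistic case models, and readers for genotype tables and VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
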