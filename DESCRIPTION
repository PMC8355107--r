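Package: prsdims
Title: Polygenic Scores, Cannabis Use and Transdiagnostic Symptom Dimensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of an analysis chain linking
    schizophrenia polygenic risk scores and cannabis use to transdiagnostic
    dimensions of psychotic symptoms and experiences. Provides bi-factor
    item-response modelling of dichotomous symptom items by marginal maximum
    likelihood (EM with Gauss-Hermite quadrature and the bi-factor dimension
    reduction), polygenic scoring from GWAS summary statistics (allele
    matching, LD clumping, p-value thresholding, Nagelkerke incremental
    pseudo R-squared, permutation empirical p-values), ancestry analysis
    (standardized genotype PCA, reference-panel k-means assignment,
    iterative-pruning substructure search, per-cluster PRS screening),
    regression-based association testing with likelihood-ratio tests and
    Benjamini-Hochberg false-discovery-rate control, and a synthetic cohort
    generator (Balding-Nichols genotypes, liability case status, latent
    symptom dimensions, two-parameter logistic item responses) so that every
    stage is testable end-to-end without access to individual-level data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
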