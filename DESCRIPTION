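Package: polygrs
Title: Population-Standardized Polygenic Risk Scores for Screening Colonoscopy Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes an odds-ratio-weighted, population-standardized polygenic
    genetic risk score (GRS) from SNP risk-allele dosages, stratifies subjects
    into low/average/elevated risk groups, and runs the downstream association
    battery used in adenoma-detection studies: univariable and multivariable
    logistic regression, Cochran-Armitage trend in detection rates across GRS
    categories, Kaplan-Meier age-at-first-adenoma analysis with log-rank
    comparison, and subgroup associations by polyp size, number and location.
    Includes readers for SNP panel TSV, genotype VCF/TSV and phenotype CSV
    files, and a synthetic-cohort generator with known ground truth for
    end-to-end validation.
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
    survival,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
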