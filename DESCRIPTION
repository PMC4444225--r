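Package: clinwgs
Title: Clinical Interpretation of Whole-Genome Sequencing Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting germline whole-genome sequencing (WGS)
    variant calls in a clinical genetics setting. Calibrates variant quality
    thresholds from replicate genotype concordance, classifies potentially
    pathogenic variants (rare nonsynonymous variants) and loss-of-function
    variants, confirms clinically diagnosed mutations, computes per-gene
    carrier fractions and burdens across patient cohorts together with a
    clinical-interpretability call ("gene variance" analysis), and provides
    exact cohort statistics (Clopper-Pearson binomial confidence intervals,
    Fisher's exact test). Includes a seeded synthetic-cohort generator that
    emulates the statistical structure of clinical WGS call sets so the whole
    pipeline is testable without protected patient data.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
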