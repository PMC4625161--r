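Package: tridosha
Title: Genotype Association and Constitutional-Type Classification for
    Three-Group Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-group genome-wide association studies in which
    each phenotype group is tested one-against-the-rest, with the
    constitutional-type (Prakriti) cohort design as the motivating case.
    Provides PLINK text PED/MAP input and output, sample and marker quality
    control (call-rate filtering, exact Hardy-Weinberg testing in controls,
    windowed linkage-disequilibrium pruning, Mendelian-inconsistency checks,
    imputation masking harnesses), allelic chi-square association with
    adaptive permutation and a survival-based true-positive filter,
    principal-component stratification control with iterative outlier
    removal, sample projection and EIGENSTRAT statistic adjustment, a
    genotype-frequency weight classifier that assigns samples to a dominant
    group, genic annotation by flanking-window overlap, and a
    Balding-Nichols synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
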