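Package: rxswitch
Title: Prescription-Switching Phenotypes and Pharmacogenetic Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives drug-switching phenotypes from longitudinal prescription
    registry records (e.g. switching between the hypnotics zopiclone and
    zolpidem, ATC codes N05CF01 and N05CF02), and runs the association
    analyses built on such phenotypes: additive-model logistic regression,
    sex-stratified effect comparison, conditional analysis at a lead variant,
    rank-based inverse-normal quantitative-trait association, composite
    linkage-disequilibrium estimation, and class-weighted Bonferroni
    significance thresholds. Includes a synthetic-data generator that
    emulates a prescription registry with known genetic effects so every
    stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
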