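Package: niptsim
Title: Simulation and Analysis of Low-Depth PCR-Free NIPT Trisomy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the fetal-fraction limit of detection of
    low-depth whole-genome-sequencing non-invasive prenatal testing (NIPT).
    Provides a seeded cell-free DNA read-count simulator (multinomial
    allocation over chromosomes with a trisomy dosage lift and calibrated
    inter-run overdispersion), a z-score aneuploidy caller against a euploid
    reference panel with the standard QC gates, chromosome-Y based fetal
    fraction estimation, an expected-fetal-fraction mixture model with an
    in-silico limit-of-detection experiment, fragment-length mixture
    simulation and zone-area statistics, and cohort-level fetal fraction
    analytics (weight and gestational-age relationships with inverse
    prediction of threshold-crossing weights). All results are tibbles and
    compose with the pipe.
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
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
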