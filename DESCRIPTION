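Package: assurbench
Title: Blinded Spiked-Panel Benchmarking of Nucleic Acid Extraction
    Technologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to design and qualify blinded specimen panels spiked with
    DNA- and RNA-based microbes, simulate replicate-level real-time RT-PCR
    detection data under a Poisson single-template model with a censored
    log-linear Ct standard curve, score extraction technologies by
    replicate-level diagnostic accuracy with exact (Clopper-Pearson) binomial
    confidence intervals, summarise volumetric efficiency of each extraction
    workflow, and rank technologies by the five-attribute ASSUR score
    (Affordable, Sensitive, Specific, User-friendly, Rapid) with min-max
    normalization and radar-plot coordinate export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
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
RoxygenNote: 7.3.3
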