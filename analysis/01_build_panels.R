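#!/usr/bin/env Rscript
# Build and qualify the three spiked specimen panels.
#
# Encodes the common ten-member layout for sputum (SP), blood (BL) and stool
# (ST) in its realized form (BL6/ST6 carry a low RNA spike), assigns blinded
# four-digit aliquot codes, and applies the qualification result: trace
# M. tuberculosis DNA in the supposedly negative SP6, which removes that
# member and its three aliquots. Writes the design and blinding map under
# results/.

suppressPackageStartupMessages(library(assurbench))
dir.create("results", showWarnings = FALSE)
seed <- 20260922

design <- build_reference_design(seed = seed, layout = "realized")
cat("Constructed design:", count_shipped_aliquots(design), "aliquots over",
    nrow(design$members), "members\n")

design <- qualify_panel(design, list(SP6 = "M. tuberculosis"))
cat("After qualification: sputum panel holds",
    sum(!design$members$excluded[design$members$panel_id == "SP"]),
    "members;", count_shipped_aliquots(design), "aliquots ship\n")

write_panel_design(design, "results/panel_design.json")
readr::write_csv(blinding_map(design), "results/blinding_map.csv")

truth <- design_truth(design)
readr::write_csv(truth, "results/panel_truth.csv")
cat("Spiked member-target channels:", sum(truth$spiked),
    "; negative channels:", sum(!truth$spiked), "\n")
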