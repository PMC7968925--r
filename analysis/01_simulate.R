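#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study --- a bait/control PSM experiment
# with 60 planted interactors (fold 8, NB dispersion 0.3, 3+3 replicates)
# and a planted-module association network over those interactors, with
# phenotype seeds placed in one module and a nonspecific (background) module.
# Everything downstream reads these files; ground truth goes to truth.json.

library(bioidnet)

seed <- 1L
outdir <- "results/fixtures"
paths <- write_fixture_bundle(outdir, preset = "default", seed = seed)

truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
message(sprintf("wrote %d fixture files to %s", length(paths), outdir))
message(sprintf("planted interactors: %d at fold %g, dispersion %g",
                length(truth$psm_truth$planted), truth$psm_truth$fold,
                truth$psm_truth$phi))
message(sprintf("network: %d nodes in blocks of %s; seeds: %s",
                length(truth$network_truth$membership),
                paste(truth$network_truth$block_sizes, collapse = "/"),
                paste(truth$network_truth$seeds, collapse = ", ")))
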