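#!/usr/bin/env Rscript
# Stage 2: call bait-specific interaction candidates from the PSM table.
# Impute missing cells to 0, sum-normalize, apply the detection filter
# (PSM > 2 in >= 2 bait replicates), estimate the common NB dispersion,
# run the per-protein likelihood-ratio test and call candidates at
# adjp < 0.05 and fold-change > 3. Performance is then scored against the
# planted truth, and the candidate set is compared with the planted set the
# way a reference-interactor overlap is scored (odds ratio + chi-squared).

library(bioidnet)

fix <- function(f) file.path("results/fixtures", f)
psm <- impute_missing(read_psm_table(fix("psm.tsv"), fix("design.tsv")))
norm <- sum_normalize(psm)
detected <- filter_detected(psm)
message(sprintf("%d/%d proteins pass the detection filter",
                length(detected), nrow(norm)))

nf <- norm[detected, , drop = FALSE]
disp <- estimate_dispersion(nf, psm$condition)
print(disp)

res <- call_candidates(lrt_differential(nf, psm$condition, disp),
                       detected = detected)
res$candidate <- as.integer(res$candidate)
dir.create("results", showWarnings = FALSE)
utils::write.table(res, "results/differential.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(fix("truth.json"), simplifyVector = TRUE)
planted <- truth$psm_truth$planted
called <- res$protein_id[res$candidate == 1]
tp <- length(intersect(called, planted))
message(sprintf("called %d candidates: recall %.0f%% of %d planted, FDR %.1f%%",
                length(called), 100 * tp / length(planted), length(planted),
                100 * (1 - tp / max(1, length(called)))))

ov <- overlap_stats(called, planted, universe_size = nrow(res))
print(ov)
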