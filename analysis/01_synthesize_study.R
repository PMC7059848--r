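#!/usr/bin/env Rscript
# Step 1: synthesize a dyadic study with known ground truth.
#
# Generates a cohort of same-sex pairs across three countries plus one
# speech-like recording per participant, with the recording's modulation
# richness tied to the speaker's closeness rating, so the acoustic pipeline
# should recover a positive articulation-space ~ closeness association.
# Audio goes under scratch/ (regenerated on demand); the manifest is the
# pipeline's input.
#
# A 12-pair study (2 pairs per country x gender cell) keeps the full
# audio pipeline quick; the statistical stages are validated at the full
# 85-pair size in 04_recovery_simulation.R, where no audio is needed.

suppressMessages(library(artispace))

study_dir <- "scratch/study"
design <- data.frame(country = rep(c("India", "Italy", "UK"), each = 2),
                     gender = rep(c("male", "female"), 3),
                     n_pairs = rep(2, 6))

manifest <- write_synthetic_study(study_dir, design = design,
                                  duration_s = 4, seed = 20260919)
cat(sprintf("Wrote %d WAV files and manifest.csv under %s\n",
            nrow(manifest), study_dir))
cat(sprintf("Pairs: %d; countries: %s\n",
            length(unique(manifest$pair_id)),
            paste(sort(unique(manifest$country)), collapse = ", ")))
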