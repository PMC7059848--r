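#!/usr/bin/env Rscript
# Step 2: acoustic feature extraction.
#
# For every manifest row: standardize the recording (mono, 22,050 Hz,
# peak-normalized to -18 dB), compute the Gaussian-window spectrogram and
# its 2-D Fourier decomposition (the speech modulation spectrum), and count
# the pixels inside the 99%-energy contour between 1 and 100 Hz temporal
# modulation -- the articulation space. Writes results/features.csv and a
# representative modulation-spectrum figure.

suppressMessages(library(artispace))

manifest_path <- "scratch/study/manifest.csv"
if (!file.exists(manifest_path)) {
  stop("run analysis/01_synthesize_study.R first")
}
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

config <- run_config(seed = 20260919)
ex <- extract_features(read.csv(manifest_path), config)
write.csv(ex$features, "results/features.csv", row.names = FALSE)

cat(sprintf("Extracted %d feature rows (%d failures)\n",
            nrow(ex$features), length(ex$failures)))
cat(sprintf("Articulation space: median %d px, range %d-%d px\n",
            round(median(ex$features$area_px)),
            min(ex$features$area_px), max(ex$features$area_px)))

# figure: SMS + contour of the participant with the largest area
top <- ex$features$participant_id[which.max(ex$features$area_px)]
manifest <- read.csv(manifest_path)
sig <- preprocess_audio(manifest$wav_path[manifest$participant_id == top],
                        config$preprocess)
mps <- normalize_mps(compute_mps(compute_spectrogram(sig)))
ct <- energy_contour(mps)
png("results/figures/sms_contour.png", width = 900, height = 600, res = 110)
plot_mps_contour(mps, ct,
                 main = sprintf("Speech modulation spectrum, %s (%d px)",
                                top, ct$area_px))
dev.off()
cat("Wrote results/features.csv and results/figures/sms_contour.png\n")
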