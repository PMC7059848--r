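#!/usr/bin/env Rscript
# Step 4: statistical validation at the full study size.
#
# Monte-Carlo recovery of the mixed model on cohorts generated at the
# study's own design (85 pairs: India 9M+13F, Italy 10M+10F, UK 18M+25F),
# with a closeness slope of 5.6 px/point, pair SD 30 and residual SD 50:
#   * bias of the closeness-slope estimate (200 replicates)
#   * coverage of its 95% confidence interval
#   * type-I error when the true slope is zero (500 replicates)
# Writes results/recovery.csv.

suppressMessages(library(artispace))
dir.create("results", showWarnings = FALSE)

betas <- default_betas(); betas["cr"] <- 5.6

reps <- 200
est <- numeric(reps); cover <- logical(reps)
for (r in seq_len(reps)) {
  coh <- generate_cohort(betas = betas, sd_pair = 30, sd_resid = 50,
                         seed = 600000 + r)
  fit <- suppressMessages(fit_hlm(coh$records))
  row <- fit$fixed_effects[fit$fixed_effects$term == "cr", ]
  est[r] <- row$estimate
  cover[r] <- row$ci_lo <= 5.6 && 5.6 <= row$ci_hi
}

null_betas <- betas; null_betas["cr"] <- 0
reject <- vapply(seq_len(500), function(r) {
  coh <- generate_cohort(betas = null_betas, sd_pair = 30, sd_resid = 50,
                         seed = 700000 + r)
  fit <- suppressMessages(fit_hlm(coh$records))
  fit$fixed_effects$p[fit$fixed_effects$term == "cr"] < 0.05
}, logical(1))

out <- data.frame(
  quantity = c("true_cr_slope", "mean_estimate", "bias", "ci95_coverage",
               "type1_error_at_null"),
  value = c(5.6, mean(est), mean(est) - 5.6, mean(cover), mean(reject)),
  n_replicates = c(NA, reps, reps, reps, 500)
)
write.csv(out, "results/recovery.csv", row.names = FALSE)
print(out, row.names = FALSE)
cat(sprintf(
  "\nAt 85 pairs the closeness slope is recovered with bias %.3f px/point,\n",
  mean(est) - 5.6))
cat(sprintf("95%% CI coverage %.3f and type-I error %.3f at the null.\n",
            mean(cover), mean(reject)))
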