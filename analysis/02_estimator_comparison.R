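#!/usr/bin/env Rscript
# Split-function estimator comparison on calibrated synthetic cohorts.
#
# Simulates 100 cohorts of 200 patients at the calibrated noise level,
# correlates each estimator-based split (ACI, SUVmean, TKA, volume)
# with the true split, and runs the Bland-Altman agreement analysis of
# the ACI split on 25-patient cohorts (the clinical study size).

library(renalpet)

dir.create("results", showWarnings = FALSE)
base_seed <- 20260921

rs <- sapply(seq_len(100), function(i) {
  co <- simulate_cohort(cohort_sim_spec(200, seed = base_seed + i))
  c(ACI = cor(co$split_aci, co$split_true),
    SUVMEAN = cor(co$split_suv, co$split_true),
    TKA = cor(co$split_tka, co$split_true),
    VOLUME = cor(co$split_vol, co$split_true))
})
cmp <- data.frame(
  estimator = rownames(rs),
  r_mean = rowMeans(rs),
  r_min = apply(rs, 1, min),
  r_max = apply(rs, 1, max),
  abs_r_mean = rowMeans(abs(rs)),
  strength = vapply(rowMeans(abs(rs)), correlation_strength, character(1))
)
write.csv(cmp, "results/estimator_comparison.csv", row.names = FALSE)
print(cmp, row.names = FALSE, digits = 3)
message(sprintf(
  "ACI split vs true split: mean r %.3f [%.3f, %.3f] over 100 cohorts; ",
  cmp$r_mean[1], cmp$r_min[1], cmp$r_max[1]),
  sprintf("ACI outperforms the SUVmean split in %d/100 cohorts.",
          sum(rs["ACI", ] > abs(rs["SUVMEAN", ]))))

agree <- sapply(seq_len(100), function(i) {
  co <- simulate_cohort(cohort_sim_spec(25, seed = base_seed + 1000 + i))
  ba <- bland_altman(co$split_aci, co$split_true, threshold = 10)
  c(mean_difference = ba$mean_difference, sd_difference = ba$sd_difference,
    n_beyond_10pt = ba$n_beyond_threshold)
})
ba_summary <- data.frame(t(rowMeans(agree)))
write.csv(ba_summary, "results/agreement_summary.csv", row.names = FALSE)
message(sprintf(
  "Bland-Altman on 25-patient cohorts: mean difference %.2f points, SD %.2f, %.1f/25 patients beyond 10 points on average.",
  ba_summary$mean_difference, ba_summary$sd_difference,
  ba_summary$n_beyond_10pt))
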