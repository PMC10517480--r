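# Correlation-to-healthy-baseline classification of the validation cohort.
#
# The healthy median baseline is the per-window median adjusted ratio of
# the validation cohort's healthy samples; every sample is scored by the
# Pearson correlation of its profile to that baseline. Low correlation
# indicates cancer. The operating cutoff maximizes sensitivity +
# specificity; the ROC sweeps all thresholds.

source("analysis/00_config.R")

disc <- cohort_summaries(strong_discovery_config())
drep <- run_discovery(disc$summaries, disc$landscape$grid)
val <- cohort_summaries(strong_validation_config(),
                        landscape = disc$landscape, index_offset = 100L)
vrep <- run_validation(val$summaries, disc$landscape$grid,
                       dmr_windows = drep$dmrs,
                       cutoffs = c(0.72, 0.76, 0.80, 0.82))

write_tsv(vrep$scores, "05_scores.tsv")
write_tsv(vrep$cutoff_table, "05_cutoff_table.tsv")
write_tsv(vrep$roc$points, "05_roc_points.tsv")
baseline <- data.frame(window = names(vrep$baseline),
                       baseline = as.numeric(vrep$baseline))
write_tsv(baseline, "05_baseline_profile.tsv")

ci <- auc_ci(vrep$scores$r, vrep$scores$group, n_boot = 2000,
             seed = BASE_SEED)
message(sprintf(
  "scored %d samples over %d windows: mean r healthy %.3f, cancer %.3f",
  nrow(vrep$scores), vrep$counts$n_selected,
  vrep$counts$mean_r_healthy, vrep$counts$mean_r_cancer))
message(sprintf(
  "chosen cutoff %.3f; AUC %.3f (bootstrap 95%% CI %.3f-%.3f)",
  vrep$cutoff, vrep$counts$auc, ci["lower"], ci["upper"]))
print(vrep$cutoff_table, row.names = FALSE)
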