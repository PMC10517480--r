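# DMR-dependent fragmentation profiles.
#
# Over the hypomethylated windows called in the strong-effect discovery
# cohort, each sample's input-adjusted short fragments ratio (window IP
# ratio divided by the genome-wide Input ratio) is assembled into the
# samples x windows profile matrix after the selection criteria: at least
# 20 deduplicated IP fragments in every sample and an adjusted ratio below
# 10 for all samples. Cancer samples show elevated adjusted ratios on these
# windows; healthy samples stay near the cohort baseline.

source("analysis/00_config.R")

disc <- cohort_summaries(strong_discovery_config())
drep <- run_discovery(disc$summaries, disc$landscape$grid)
message(sprintf("discovery: %d hypo windows called, %d pass selection",
                drep$counts$n_hypo, drep$counts$n_selected_hypo))

val <- cohort_summaries(strong_validation_config(),
                        landscape = disc$landscape, index_offset = 100L)
sel <- select_informative_windows(val$summaries, drep$dmrs, "HYPO")
prof <- build_profile_matrix(val$summaries, sel)

long <- data.frame(
  sample = rep(rownames(prof), times = ncol(prof)),
  group = rep(attr(prof, "groups"), times = ncol(prof)),
  window = rep(colnames(prof), each = nrow(prof)),
  adjusted_ratio = as.vector(prof))
write_tsv(long, "04_profile_matrix_long.tsv")

hypo_truth <- disc$landscape$grid$windows$id[disc$landscape$hypo]
by_group <- tapply(long$adjusted_ratio, long$group, mean)
message(sprintf(
  "validation profiles over %d selected windows (%d of them planted hypo): mean adjusted ratio healthy %.3f vs cancer %.3f",
  length(sel), sum(sel %in% hypo_truth), by_group["healthy"], by_group["cancer"]))
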