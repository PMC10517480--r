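# Shared configuration of the analysis workflow. Each numbered script is a
# standalone driver: it regenerates what it needs from these seeded
# configurations, so any script can be run on its own.

library(medipfrag)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

BASE_SEED <- 20240901L

# the study conditions: discovery-style cohort of 3 healthy vs 3 cancer
# samples, 200k Input fragments each, 2000 10-kb windows, 200 + 200 planted
default_config <- function() sim_config(seed = BASE_SEED)

# the high tumor-burden, deeply sequenced preset used for the classifier
strong_discovery_config <- function() strong_effect_config(seed = BASE_SEED + 1L)
strong_validation_config <- function()
  strong_effect_config(seed = BASE_SEED + 1L, n_healthy = 8L, n_cancer = 11L)

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  data.table::fwrite(df, path, sep = "\t")
  message("wrote ", path)
  invisible(path)
}
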