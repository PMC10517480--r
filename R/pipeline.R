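#' Run the discovery-stage analysis
#'
#' End-to-end over one cohort's sample summaries: builds the IP count
#' matrix, calls differentially methylated windows, applies the
#' window-selection criteria to both DMR classes and assembles the
#' hypomethylated-window fragmentation profile matrix, together with the
#' cohort-level fragment-size statistics.
#'
#' @param summaries List of `sample_summary` objects (see
#'   [summarize_sample()] / [cohort_summaries()]).
#' @param grid The [window_grid()] the summaries were computed on.
#' @param min_mean Mean-count filter threshold (default 10).
#' @param alpha,lfc,use_padj DMR thresholds, see [classify_dmrs()].
#' @param min_fragments,max_adjusted_ratio Window-selection criteria, see
#'   [select_informative_windows()].
#' @param denominator Adjusted-ratio denominator mode.
#' @return A run report list: `dmrs`, `selected_hypo`, `selected_hyper`,
#'   `profiles` (adjusted-ratio matrix over selected hypo windows, `NULL`
#'   when none), `sample_stats`, and a `counts` block whose entries
#'   reconcile (windows tested = kept + filtered, etc.).
#' @export
run_discovery <- function(summaries, grid, min_mean = 10, alpha = 0.05,
                          lfc = 1, use_padj = TRUE, min_fragments = 20,
                          max_adjusted_ratio = 10,
                          denominator = "genome_input") {
  groups <- vapply(summaries, `[[`, character(1), "group")
  for (cls in c("healthy", "cancer"))
    if (!any(groups == cls))
      stop("discovery requires both groups; '", cls, "' is empty")
  cm <- build_count_matrix(summaries, grid)
  cm_f <- filter_low_count_windows(cm, min_mean)
  if (nrow(cm_f$counts) == 0) stop("no windows pass the mean-count filter")
  sf <- estimate_size_factors(cm_f)
  dmrs <- classify_dmrs(nb_window_test(cm_f, sf), alpha = alpha, lfc = lfc,
                        use_padj = use_padj)
  sel_hypo <- select_informative_windows(summaries, dmrs, "HYPO",
                                         min_fragments, max_adjusted_ratio,
                                         denominator)
  sel_hyper <- select_informative_windows(summaries, dmrs, "HYPER",
                                          min_fragments, max_adjusted_ratio,
                                          denominator)
  profiles <- if (length(sel_hypo) > 0)
    build_profile_matrix(summaries, sel_hypo, denominator) else NULL
  sample_stats <- data.frame(
    sample = vapply(summaries, `[[`, character(1), "sample_id"),
    group = groups,
    n_input = vapply(summaries, `[[`, numeric(1), "n_input"),
    n_ip = vapply(summaries, `[[`, numeric(1), "n_ip"),
    input_ratio = vapply(summaries, `[[`, numeric(1), "input_ratio"),
    ip_ratio = vapply(summaries, `[[`, numeric(1), "ip_ratio"),
    pct_change = vapply(summaries, ratio_change_ip_vs_input, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(
    dmrs = dmrs, size_factors = sf,
    selected_hypo = sel_hypo, selected_hyper = sel_hyper,
    profiles = profiles, sample_stats = sample_stats,
    counts = list(
      n_samples = length(summaries),
      windows_total = grid$n_windows,
      windows_filtered = grid$n_windows - nrow(cm_f$counts),
      windows_tested = nrow(cm_f$counts),
      n_hyper = sum(dmrs$class == "HYPER"),
      n_hypo = sum(dmrs$class == "HYPO"),
      n_selected_hypo = length(sel_hypo),
      n_selected_hyper = length(sel_hyper)
    )
  )
}

#' Run the validation-stage analysis
#'
#' Builds per-sample fragmentation profiles over hypomethylated DMR
#' windows, the healthy median baseline, Pearson scores, the chosen cutoff
#' with its sensitivity/specificity table, and the ROC curve. Windows are
#' either supplied (`dmr_windows`, e.g. discovery-trained) or called within
#' the cohort (`dmr_windows = NULL`); in both cases the selection criteria
#' are applied against the validation samples.
#'
#' @param summaries List of `sample_summary` objects of the validation
#'   cohort.
#' @param grid The [window_grid()].
#' @param dmr_windows Optional `dmr_result` to reuse; when `NULL` DMRs are
#'   called within the cohort.
#' @param leave_one_out Score healthy samples against a baseline excluding
#'   themselves.
#' @param cutoffs Optional extra cutoffs for the reported table (the chosen
#'   cutoff is always included).
#' @inheritParams run_discovery
#' @return A run report list: `selected_windows`, `profiles`, `baseline`,
#'   `scores` (with predicted labels), `cutoff`, `cutoff_table`, `roc`,
#'   and a `counts` block.
#' @export
run_validation <- function(summaries, grid, dmr_windows = NULL,
                           min_mean = 10, alpha = 0.05, lfc = 1,
                           use_padj = TRUE, min_fragments = 20,
                           max_adjusted_ratio = 10,
                           denominator = "genome_input",
                           leave_one_out = FALSE, cutoffs = NULL) {
  groups <- vapply(summaries, `[[`, character(1), "group")
  if (!any(groups == "healthy"))
    stop("validation requires healthy samples (baseline undefined)")
  dmrs <- if (is.null(dmr_windows)) {
    cm <- build_count_matrix(summaries, grid)
    call_dmrs(cm, min_mean = min_mean, alpha = alpha, lfc = lfc,
              use_padj = use_padj)
  } else dmr_windows
  stopifnot(inherits(dmrs, "dmr_result"))
  sel <- select_informative_windows(summaries, dmrs, "HYPO", min_fragments,
                                    max_adjusted_ratio, denominator)
  if (length(sel) == 0) stop("no hypomethylated windows pass selection")
  profiles <- build_profile_matrix(summaries, sel, denominator)
  healthy_ids <- rownames(profiles)[attr(profiles, "groups") == "healthy"]
  baseline <- healthy_median_baseline(profiles, healthy_ids)
  scores <- score_samples(profiles, baseline, leave_one_out = leave_one_out,
                          healthy_ids = healthy_ids)
  have_cancer <- any(groups == "cancer")
  if (have_cancer) {
    cutoff <- choose_cutoff(scores$r, scores$group)
    scores$predicted <- classify_score(scores$r, cutoff)
    tab <- cutoff_table(scores$r, scores$group,
                        sort(unique(c(cutoffs, cutoff)), decreasing = TRUE))
    roc <- roc_auc(scores$r, scores$group)
  } else {
    cutoff <- NA_real_; tab <- NULL; roc <- NULL
  }
  list(
    dmrs = dmrs, selected_windows = sel, profiles = profiles,
    baseline = baseline, scores = scores, cutoff = cutoff,
    cutoff_table = tab, roc = roc,
    counts = list(
      n_samples = length(summaries),
      n_healthy = sum(groups == "healthy"),
      n_cancer = sum(groups == "cancer"),
      n_selected = length(sel),
      mean_r_healthy = mean(scores$r[scores$group == "healthy"]),
      mean_r_cancer = if (have_cancer)
        mean(scores$r[scores$group == "cancer"]) else NA_real_,
      auc = if (have_cancer) roc$auc else NA_real_
    )
  )
}
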