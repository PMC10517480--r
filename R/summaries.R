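#' Summarize one sample's paired libraries over a window grid
#'
#' Reduces a sample's Input and IP fragment sets to the per-window short and
#' long fragment counts (midpoint assignment, 100-220 bp), the length
#' histograms, and the genome-wide short fragments ratios. All downstream
#' statistics (window counts for DMR calling, input-adjusted ratios,
#' classifier profiles) are functions of this summary, so cohorts can be
#' processed sample-by-sample without keeping fragments in memory.
#'
#' Deduplication and size filtering are applied here unless the sets are
#' already marked deduplicated.
#'
#' @param input,ip [fragment_set()]s of the sample's Input and IP libraries.
#' @param grid A [window_grid()].
#' @param group Cohort label, `"healthy"` or `"cancer"`.
#' @param short_max,size_range Short/long boundary and analysis size range.
#' @return A `sample_summary`: per-window count table `win` (short_ip,
#'   long_ip, short_in, long_in), histograms, totals and genome-wide ratios.
#' @export
summarize_sample <- function(input, ip, grid, group = c("healthy", "cancer"),
                             short_max = 150L, size_range = c(100L, 220L)) {
  stopifnot(inherits(input, "fragment_set"), inherits(ip, "fragment_set"),
            inherits(grid, "window_grid"))
  group <- match.arg(group)
  prep <- function(fs) {
    if (!fs$dedup_applied) fs <- deduplicate(fs)
    filter_size_range(fs, size_range[1], size_range[2])
  }
  input <- prep(input); ip <- prep(ip)
  count2 <- function(fs) {
    idx <- window_index(fs$records$chrom, fs$records$start, fs$records$end, grid)
    is_short <- fs$records$length <= short_max
    cbind(short = tabulate(idx[is_short], nbins = grid$n_windows),
          long = tabulate(idx[!is_short], nbins = grid$n_windows))
  }
  cin <- count2(input); cip <- count2(ip)
  win <- data.frame(id = grid$windows$id,
                    short_ip = cip[, "short"], long_ip = cip[, "long"],
                    short_in = cin[, "short"], long_in = cin[, "long"],
                    stringsAsFactors = FALSE)
  structure(list(
    sample_id = input$sample_id, group = group, win = win,
    n_input = n_fragments(input), n_ip = n_fragments(ip),
    hist_input = size_distribution(input, size_range),
    hist_ip = size_distribution(ip, size_range),
    input_ratio = short_fragments_ratio(input, short_max = short_max,
                                        size_range = size_range)$ratio,
    ip_ratio = short_fragments_ratio(ip, short_max = short_max,
                                     size_range = size_range)$ratio,
    short_max = as.integer(short_max), size_range = as.integer(size_range)
  ), class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("<sample_summary> ", x$sample_id, " (", x$group, "): ",
      format(x$n_input, big.mark = ","), " Input / ",
      format(x$n_ip, big.mark = ","), " IP fragments over ",
      nrow(x$win), " windows\n", sep = "")
  invisible(x)
}

#' Summarize a simulated sample
#'
#' @param sample A `simulated_sample` with both libraries generated.
#' @inheritParams summarize_sample
#' @return A `sample_summary`.
#' @export
summarize_simulated_sample <- function(sample, grid, short_max = 150L,
                                       size_range = c(100L, 220L)) {
  stopifnot(inherits(sample, "simulated_sample"))
  if (is.null(sample$ip)) stop("IP library not generated; run apply_ip_capture()")
  summarize_sample(sample$input, sample$ip, grid, sample$group,
                   short_max, size_range)
}

#' Simulate a cohort and reduce it to per-sample summaries
#'
#' Memory-light driver: generates each sample on its seeded stream,
#' summarizes it over the landscape's window grid, and discards the
#' fragments. Equivalent to `simulate_cohort()` followed by
#' `summarize_simulated_sample()` on every sample.
#'
#' @inheritParams simulate_cohort
#' @return List with `config`, `landscape` and `summaries` (list of
#'   `sample_summary`).
#' @export
cohort_summaries <- function(cfg, landscape = NULL, index_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(landscape)) landscape <- build_landscape(cfg)
  groups <- c(rep("healthy", cfg$n_healthy), rep("cancer", cfg$n_cancer))
  ids <- c(sprintf("H%d", seq_len(cfg$n_healthy)),
           sprintf("P%d", seq_len(cfg$n_cancer)))
  summaries <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- simulate_sample(cfg, landscape, groups[i], ids[i],
                         index = index_offset + i)
    summaries[[i]] <- summarize_simulated_sample(s, landscape$grid,
                                                 cfg$short_max, cfg$size_range)
  }
  names(summaries) <- ids
  list(config = cfg, landscape = landscape, summaries = summaries)
}
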