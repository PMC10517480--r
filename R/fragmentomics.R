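#' Short/long fragment counts and ratio
#'
#' The short fragments ratio is the count of short cfDNA fragments (100-150
#' bp) divided by the count of long fragments (151-220 bp) in a library or
#' region. With no long fragments the ratio is undefined and carried as
#' `NA` (not zero, which would bias window selection); with no short
#' fragments it is 0.
#'
#' @param n_short,n_long Nonnegative integer counts.
#' @return A `ratio_result`: list with `n_short`, `n_long`, `ratio`.
#' @export
ratio_result <- function(n_short, n_long) {
  stopifnot(n_short >= 0, n_long >= 0)
  structure(list(n_short = as.integer(n_short), n_long = as.integer(n_long),
                 ratio = if (n_long > 0) n_short / n_long else NA_real_),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat("<ratio_result> short ", x$n_short, " / long ", x$n_long, " = ",
      if (is.na(x$ratio)) "undefined" else format(x$ratio, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Fragment size histogram
#'
#' Exact integer histogram of fragment lengths over the analysis range.
#' Densities are obtained by dividing counts by the total, i.e. they
#' normalize within the 100-220 bp analysis range.
#'
#' @param fs A [fragment_set()], already filtered to the size range.
#' @param size_range Inclusive length bounds in bp.
#' @return A `size_distribution`: integer `counts` named by length, `total`.
#' @export
size_distribution <- function(fs, size_range = c(100L, 220L)) {
  stopifnot(inherits(fs, "fragment_set"))
  len <- fs$records$length
  if (length(len) > 0 && (min(len) < size_range[1] || max(len) > size_range[2]))
    stop("fragment lengths outside ", size_range[1], "-", size_range[2],
         " bp; apply filter_size_range() first")
  lengths <- seq.int(size_range[1], size_range[2])
  counts <- tabulate(factor(len, levels = lengths), nbins = length(lengths))
  names(counts) <- lengths
  structure(list(counts = counts, total = length(len),
                 size_range = as.integer(size_range)),
            class = "size_distribution")
}

#' Mean fragment size
#'
#' @param fs A nonempty [fragment_set()].
#' @return Arithmetic mean length in bp.
#' @export
mean_size <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  if (nrow(fs$records) == 0) stop("mean size undefined for an empty fragment set")
  mean(fs$records$length)
}

#' Short fragments ratio of a library or region
#'
#' Counts short (100-150 bp) and long (151-220 bp) fragments, optionally
#' restricted to a set of genome windows (fragments are attributed to
#' windows by the same midpoint rule used for counting, keeping ratio and
#' count computations consistent). The boundary is exact: a 150 bp fragment
#' is short, a 151 bp fragment is long.
#'
#' @param fs A [fragment_set()].
#' @param grid A [window_grid()]; required when `windows` is given.
#' @param windows Optional character vector of window ids restricting the
#'   counts.
#' @param short_max Largest "short" length (default 150).
#' @param size_range Analysis range; fragments outside it are ignored.
#' @return A [ratio_result()].
#' @export
short_fragments_ratio <- function(fs, grid = NULL, windows = NULL,
                                  short_max = 150L, size_range = c(100L, 220L)) {
  stopifnot(inherits(fs, "fragment_set"))
  len <- fs$records$length
  keep <- len >= size_range[1] & len <= size_range[2]
  if (!is.null(windows)) {
    if (is.null(grid)) stop("grid is required when restricting to windows")
    idx <- window_index(fs$records$chrom, fs$records$start, fs$records$end, grid)
    keep <- keep & grid$windows$id[idx] %in% windows
  }
  len <- len[keep]
  ratio_result(sum(len <= short_max), sum(len > short_max))
}

#' Genome-binned fragmentation profile
#'
#' Per-bin short fragments ratio across the genome (default 5-Mb bins),
#' computed without GC adjustment. Bins with no long fragments carry an
#' undefined (`NA`) ratio.
#'
#' @param fs A deduplicated, size-filtered [fragment_set()].
#' @param layout A [genome_layout()].
#' @param bin_bp Bin size in bp (default 5 Mb).
#' @inheritParams short_fragments_ratio
#' @return A `genome_bin_profile`: data.frame with chrom, start, end,
#'   n_short, n_long, ratio; attribute `bin_bp`.
#' @export
genome_bin_profile <- function(fs, layout, bin_bp = 5e6, short_max = 150L,
                               size_range = c(100L, 220L)) {
  stopifnot(inherits(fs, "fragment_set"), inherits(layout, "genome_layout"))
  grid <- window_grid(layout, bin_bp)
  len <- fs$records$length
  keep <- len >= size_range[1] & len <= size_range[2]
  r <- fs$records[keep, , drop = FALSE]
  idx <- window_index(r$chrom, r$start, r$end, grid)
  nb <- grid$n_windows
  n_short <- tabulate(idx[r$length <= short_max], nbins = nb)
  n_long <- tabulate(idx[r$length > short_max], nbins = nb)
  out <- grid$windows[c("chrom", "start", "end")]
  out$n_short <- n_short
  out$n_long <- n_long
  out$ratio <- ifelse(n_long > 0, n_short / n_long, NA_real_)
  structure(out, bin_bp = bin_bp, class = c("genome_bin_profile", "data.frame"))
}

#' IP minus Input per-bin profile difference
#'
#' Subtracts the Input short fragments ratio from the IP ratio in each
#' genome bin; the IP reaction depletes poorly methylated fragments, so
#' negative deltas indicate loss of short fragments during capture.
#'
#' @param ip,input [genome_bin_profile()]s on the same bin grid.
#' @return Numeric vector of per-bin deltas (`NA` where either side is
#'   undefined).
#' @export
profile_delta <- function(ip, input) {
  stopifnot(inherits(ip, "genome_bin_profile"),
            inherits(input, "genome_bin_profile"))
  if (!identical(ip$chrom, input$chrom) || !identical(ip$start, input$start) ||
      !identical(ip$end, input$end))
    stop("bin grids of the two profiles do not match")
  ip$ratio - input$ratio
}

#' Percent change between two ratios
#'
#' `100 * (hypo_ratio - hyper_ratio) / hyper_ratio`: the relative excess of
#' the short fragments ratio in hypomethylated over hypermethylated regions.
#'
#' @param hypo_ratio,hyper_ratio Short fragments ratios; `hyper_ratio` must
#'   be positive.
#' @return Percent change (real, on the percent scale).
#' @export
percent_change <- function(hypo_ratio, hyper_ratio) {
  if (!is.finite(hyper_ratio) || hyper_ratio <= 0)
    stop("percent change undefined: reference ratio must be positive")
  100 * (hypo_ratio - hyper_ratio) / hyper_ratio
}

#' Percent change of the short fragments ratio, IP vs Input
#'
#' `100 * (ratio_IP - ratio_Input) / ratio_Input` for one sample's paired
#' libraries.
#'
#' @param sample A `sample_summary` (see [summarize_sample()]) or a
#'   `simulated_sample` with both libraries present.
#' @return Percent change (real).
#' @export
ratio_change_ip_vs_input <- function(sample) {
  if (inherits(sample, "sample_summary")) {
    r_ip <- sample$ip_ratio
    r_in <- sample$input_ratio
  } else if (inherits(sample, "simulated_sample")) {
    if (is.null(sample$ip)) stop("IP library not generated")
    r_ip <- short_fragments_ratio(sample$ip)$ratio
    r_in <- short_fragments_ratio(sample$input)$ratio
  } else stop("expected a sample_summary or simulated_sample")
  if (!is.finite(r_in) || r_in <= 0)
    stop("percent change undefined: Input ratio must be positive")
  percent_change(r_ip, r_in)
}
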