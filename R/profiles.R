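#' Genome-wide short fragments ratio of a sample's Input library
#'
#' The denominator of the input-adjusted ratio: the short fragments ratio
#' over the sample's entire Input library.
#'
#' @param sample A `sample_summary` (see [summarize_sample()]).
#' @return Positive real ratio.
#' @export
genome_wide_input_ratio <- function(sample) {
  stopifnot(inherits(sample, "sample_summary"))
  r <- sample$input_ratio
  if (!is.finite(r)) stop("genome-wide Input ratio undefined (no long fragments)")
  r
}

#' Input-adjusted short fragments ratio of a window
#'
#' The window's IP short fragments ratio divided by the genome-wide short
#' fragments ratio of the sample's matched Input library. This adjustment
#' removes the sample-level bias in short-fragment abundance present before
#' immunoprecipitation. An alternative per-window Input denominator is
#' available for sensitivity analysis (`denominator = "window_input"`).
#'
#' @param sample A `sample_summary`.
#' @param window Window id (or vector of ids).
#' @param denominator `"genome_input"` (default) or `"window_input"`.
#' @return Adjusted ratio(s); `NA` where a component is undefined.
#' @export
input_adjusted_ratio <- function(sample, window,
                                 denominator = c("genome_input", "window_input")) {
  stopifnot(inherits(sample, "sample_summary"))
  denominator <- match.arg(denominator)
  i <- match(window, sample$win$id)
  if (anyNA(i)) stop("unknown window id(s): ",
                     paste(window[is.na(i)], collapse = ", "))
  ip <- ifelse(sample$win$long_ip[i] > 0,
               sample$win$short_ip[i] / sample$win$long_ip[i], NA_real_)
  den <- if (denominator == "genome_input") {
    genome_wide_input_ratio(sample)
  } else {
    ifelse(sample$win$long_in[i] > 0,
           sample$win$short_in[i] / sample$win$long_in[i], NA_real_)
  }
  out <- ip / den
  out[!is.finite(out)] <- NA_real_
  unname(out)
}

#' Select informative DMR windows
#'
#' Applies the window-selection criteria to DMR windows of the requested
#' class: every sample (across both cohorts given) must have at least
#' `min_fragments` deduplicated IP fragments in the window, and an
#' input-adjusted short fragments ratio defined and below
#' `max_adjusted_ratio`. Output order is deterministic (chromosome, start).
#'
#' @param samples List of `sample_summary` objects (all samples that must
#'   satisfy the criteria).
#' @param dmrs A `dmr_result` (see [classify_dmrs()]).
#' @param class DMR class to select, `"HYPO"` (default; the diagnostic
#'   feature space) or `"HYPER"`.
#' @param min_fragments Minimum deduplicated IP fragments per window per
#'   sample (default 20).
#' @param max_adjusted_ratio Upper bound (exclusive) on the input-adjusted
#'   ratio for every sample (default 10).
#' @param denominator Passed to [input_adjusted_ratio()].
#' @return Character vector of window ids.
#' @export
select_informative_windows <- function(samples, dmrs, class = c("HYPO", "HYPER"),
                                       min_fragments = 20,
                                       max_adjusted_ratio = 10,
                                       denominator = "genome_input") {
  class <- match.arg(class)
  stopifnot(inherits(dmrs, "dmr_result"))
  cand <- dmrs[dmrs$class == class, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
  ids <- cand$id
  if (length(ids) == 0) return(character(0))
  keep <- rep(TRUE, length(ids))
  for (s in samples) {
    i <- match(ids, s$win$id)
    frag <- s$win$short_ip[i] + s$win$long_ip[i]
    adj <- input_adjusted_ratio(s, ids, denominator = denominator)
    keep <- keep & frag >= min_fragments & !is.na(adj) &
      adj < max_adjusted_ratio
  }
  ids[keep]
}

#' Per-sample fragmentation profile matrix
#'
#' Input-adjusted short fragments ratios, samples x selected windows. On
#' windows passing [select_informative_windows()] for the same samples the
#' matrix is complete; any missing entry raises an internal consistency
#' error.
#'
#' @param samples List of `sample_summary` objects.
#' @param windows Character vector of selected window ids (column order).
#' @param denominator Passed to [input_adjusted_ratio()].
#' @return An `adjusted_ratio_matrix`: numeric matrix with sample ids as
#'   rows, window ids as columns, and a `groups` attribute.
#' @export
build_profile_matrix <- function(samples, windows,
                                 denominator = "genome_input") {
  if (length(windows) == 0) stop("no windows selected")
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  mat <- matrix(unlist(lapply(samples, function(s)
    input_adjusted_ratio(s, windows, denominator = denominator))),
    nrow = length(samples), ncol = length(windows), byrow = TRUE,
    dimnames = list(ids, windows))
  if (anyNA(mat))
    stop("internal consistency error: missing adjusted ratio after selection")
  structure(mat, groups = stats::setNames(
    vapply(samples, `[[`, character(1), "group"), ids),
    class = c("adjusted_ratio_matrix", "matrix", "array"))
}
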