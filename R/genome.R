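#' Genome layout
#'
#' An ordered set of chromosome names with lengths in bp. All coordinates in
#' the package are 0-based half-open.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp. Names are
#'   chromosome names; order is preserved.
#' @return A `genome_layout` object.
#' @examples
#' genome_layout(c(chr1 = 1e7, chr2 = 1e7))
#' @export
genome_layout <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(
    list(chrom = names(lengths), length = as.numeric(unname(lengths))),
    class = "genome_layout"
  )
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Tab-separated file with columns chromosome name and length.
#' @return A [genome_layout()] object.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  lens <- tab$length
  names(lens) <- tab$chrom
  genome_layout(lens)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom), " chromosomes, ",
      format(sum(x$length), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Nonoverlapping window tiling of a genome
#'
#' Tiles each chromosome with nonoverlapping windows of `window_bp` base
#' pairs starting at 0; the last window of a chromosome may be shorter.
#' Window ids are `"chrom:start-end"` in 0-based half-open coordinates.
#'
#' @param layout A [genome_layout()].
#' @param window_bp Window size in bp (default 10 kb, the resolution used for
#'   differential-methylation calling).
#' @return A `window_grid` object with a `windows` data.frame
#'   (chrom, start, end, id) and per-chromosome index offsets.
#' @export
window_grid <- function(layout, window_bp = 10000L) {
  stopifnot(inherits(layout, "genome_layout"))
  window_bp <- as.integer(window_bp)
  if (window_bp <= 0) stop("window_bp must be positive")
  n_win <- ceiling(layout$length / window_bp)
  chrom <- rep(layout$chrom, n_win)
  idx <- unlist(lapply(n_win, function(n) seq_len(n) - 1L), use.names = FALSE)
  start <- idx * window_bp
  end <- pmin(start + window_bp, rep(layout$length, n_win))
  windows <- data.frame(
    chrom = chrom, start = start, end = end,
    id = paste0(chrom, ":", start, "-", end),
    stringsAsFactors = FALSE
  )
  offset <- c(0, cumsum(n_win))[seq_along(layout$chrom)]
  names(offset) <- layout$chrom
  structure(
    list(layout = layout, window_bp = window_bp, windows = windows,
         offset = offset, n_windows = nrow(windows)),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat("<window_grid> ", x$n_windows, " windows of ", x$window_bp, " bp over ",
      length(x$layout$chrom), " chromosomes\n", sep = "")
  invisible(x)
}

# Global window index (1-based into grid$windows) of fragment midpoints.
# Midpoint = floor((start + end) / 2); each fragment maps to exactly one
# window. Errors on chromosomes absent from the grid's layout.
window_index <- function(chrom, start, end, grid) {
  stopifnot(inherits(grid, "window_grid"))
  bad <- setdiff(unique(chrom), grid$layout$chrom)
  if (length(bad) > 0)
    stop("fragment chromosome(s) absent from genome layout: ",
         paste(bad, collapse = ", "))
  mid <- (start + end) %/% 2
  as.integer(grid$offset[chrom] + mid %/% grid$window_bp + 1L)
}
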