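#' Construct a fragment set
#'
#' A fragment set holds the cfDNA molecules of one sequencing library of one
#' sample. Each record is one sequenced molecule: chromosome, 0-based
#' half-open start/end, molecular barcode (possibly empty) and derived
#' length `end - start`. Fragments are strandless intervals.
#'
#' @param records data.frame with columns `chrom`, `start`, `end` and
#'   optionally `barcode`.
#' @param sample_id Sample identifier.
#' @param library `"INPUT"` or `"IP"` (pre- vs post-5mC-immunoprecipitation).
#' @param dedup_applied Whether PCR-duplicate removal has been applied.
#' @return A `fragment_set` object.
#' @export
fragment_set <- function(records, sample_id, library = c("INPUT", "IP"),
                         dedup_applied = FALSE) {
  library <- match.arg(library)
  if (is.null(records$barcode)) records$barcode <- rep("", nrow(records))
  records <- data.frame(
    chrom = as.character(records$chrom),
    start = as.integer(records$start),
    end = as.integer(records$end),
    barcode = as.character(records$barcode),
    stringsAsFactors = FALSE
  )
  if (nrow(records) > 0 && any(records$end <= records$start))
    stop("invalid fragment record: end <= start")
  records$length <- records$end - records$start
  structure(
    list(sample_id = sample_id, library = library, records = records,
         dedup_applied = dedup_applied),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> ", x$sample_id, " [", x$library, "] ",
      format(nrow(x$records), big.mark = ","), " fragments",
      if (x$dedup_applied) ", deduplicated" else "", "\n", sep = "")
  invisible(x)
}

#' Number of fragments in a set
#' @param fs A [fragment_set()].
#' @return Integer count of records.
#' @export
n_fragments <- function(fs) nrow(fs$records)

#' Read a BED-like fragment table
#'
#' Reads a headerless tab-separated table with columns chromosome, start,
#' end and optionally molecular barcode (0-based half-open coordinates).
#' No filtering is applied; records are returned in file order. A missing
#' barcode column yields empty barcodes.
#'
#' @param path File path.
#' @inheritParams fragment_set
#' @return A [fragment_set()].
#' @export
read_fragment_table <- function(path, sample_id, library = c("INPUT", "IP")) {
  library <- match.arg(library)
  tab <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = list(character = 1), data.table = FALSE)
  if (ncol(tab) < 3)
    stop("fragment table must have at least 3 columns (chrom, start, end)")
  names(tab)[1:3] <- c("chrom", "start", "end")
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0 || anyNA(v))
      stop(sprintf("parse error at line %d: non-integer %s coordinate",
                   if (length(bad) > 0) bad[1] else which(is.na(v))[1], col))
    tab[[col]] <- v
  }
  bad <- which(tab$end <= tab$start)
  if (length(bad) > 0)
    stop(sprintf("parse error at line %d: end <= start (degenerate interval)",
                 bad[1]))
  barcode <- if (ncol(tab) >= 4) as.character(tab[[4]]) else ""
  fragment_set(
    data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
               barcode = barcode, stringsAsFactors = FALSE),
    sample_id = sample_id, library = library
  )
}

#' Write a fragment set as a BED-like table
#'
#' Tab-separated, headerless: chrom, start, end, barcode. Round-trips with
#' [read_fragment_table()].
#'
#' @param fs A [fragment_set()].
#' @param path Output file path.
#' @export
write_fragment_table <- function(fs, path) {
  stopifnot(inherits(fs, "fragment_set"))
  data.table::fwrite(fs$records[c("chrom", "start", "end", "barcode")],
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract fragments from paired-end alignments
#'
#' Builds one fragment per retained read pair, spanning the leftmost start to
#' the rightmost end of the pair. Pairs are dropped when the proper-pair flag
#' is unset, either mate's mapping quality is below `min_mapq` (the
#' operational criterion for "uniquely mapped"), or the insert is shorter
#' than `min_insert` bp. Secondary and supplementary alignments are ignored;
#' unpaired orphan reads are counted, skipped and reported with a warning.
#'
#' @param path BAM file of paired-end alignments.
#' @inheritParams fragment_set
#' @param min_insert Minimum insert size in bp; pairs below it are eliminated
#'   (default 20).
#' @param min_mapq Minimum mapping quality for both mates (default 30).
#' @param barcode_from Where the molecular barcode lives: `"name"` takes the
#'   leading token of the read name (before `barcode_sep`), `"tag"` reads the
#'   BAM tag named in `barcode_tag`, `"none"` leaves barcodes empty.
#' @param barcode_sep Separator after the barcode token in read names.
#' @param barcode_tag BAM tag holding the barcode when `barcode_from = "tag"`.
#' @return A [fragment_set()] with attribute `"dropped"`: named counts of
#'   pairs dropped per reason (`not_proper`, `low_mapq`, `short_insert`) and
#'   orphan reads.
#' @export
fragments_from_paired_alignments <- function(path, sample_id,
                                             library = c("INPUT", "IP"),
                                             min_insert = 20L, min_mapq = 30L,
                                             barcode_from = c("name", "tag", "none"),
                                             barcode_sep = ":",
                                             barcode_tag = "BC") {
  library <- match.arg(library)
  barcode_from <- match.arg(barcode_from)
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read BAM files")
  what <- c("qname", "flag", "rname", "pos", "mapq", "isize")
  param <- Rsamtools::ScanBamParam(
    what = what,
    tag = if (barcode_from == "tag") barcode_tag else character(0),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  n_reads <- length(res$qname)
  dropped <- c(orphan = 0L, not_proper = 0L, low_mapq = 0L, short_insert = 0L)
  if (n_reads == 0) {
    fs <- fragment_set(data.frame(chrom = character(), start = integer(),
                                  end = integer(), barcode = character()),
                       sample_id, library)
    attr(fs, "dropped") <- dropped
    return(fs)
  }
  tab <- table(res$qname)
  paired_q <- names(tab)[tab == 2L]
  orphans <- n_reads - 2L * length(paired_q)
  if (orphans > 0) {
    dropped["orphan"] <- orphans
    warning(orphans, " orphan read(s) without a mate were skipped")
  }
  keep <- res$qname %in% paired_q
  idx <- which(keep)[order(match(res$qname[keep], paired_q), res$pos[keep])]
  first <- idx[seq(1, length(idx), by = 2)]   # leftmost mate of each pair
  second <- idx[seq(2, length(idx), by = 2)]
  proper <- bitwAnd(res$flag[first], 2L) > 0L
  mapq_ok <- res$mapq[first] >= min_mapq & res$mapq[second] >= min_mapq
  mapq_ok[is.na(mapq_ok)] <- FALSE
  insert <- abs(res$isize[first])
  insert_ok <- insert >= min_insert
  dropped["not_proper"] <- sum(!proper)
  dropped["low_mapq"] <- sum(proper & !mapq_ok)
  dropped["short_insert"] <- sum(proper & mapq_ok & !insert_ok)
  sel <- proper & mapq_ok & insert_ok
  f <- first[sel]
  barcode <- switch(barcode_from,
    name = vapply(strsplit(res$qname[f], barcode_sep, fixed = TRUE),
                  `[`, character(1), 1L),
    tag = {
      tg <- res$tag[[barcode_tag]]
      if (is.null(tg)) rep("", length(f)) else as.character(tg[f])
    },
    none = rep("", length(f))
  )
  fs <- fragment_set(
    data.frame(chrom = as.character(res$rname[f]),
               start = res$pos[f] - 1L,                 # BAM pos is 1-based
               end = res$pos[f] - 1L + insert[sel],
               barcode = barcode, stringsAsFactors = FALSE),
    sample_id = sample_id, library = library
  )
  attr(fs, "dropped") <- dropped
  fs
}

#' Remove PCR duplicates
#'
#' PCR duplicates are records sharing the same genomic start, end and
#' molecular barcode; exactly one record (the first encountered) is retained
#' per (chrom, start, end, barcode) key. Idempotent.
#'
#' @param fs A [fragment_set()].
#' @return Deduplicated [fragment_set()] with `dedup_applied = TRUE` and
#'   attribute `"n_duplicates"` holding the number of removed records.
#' @export
deduplicate <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  r <- fs$records
  dup <- duplicated(r[c("chrom", "start", "end", "barcode")])
  out <- fragment_set(r[!dup, , drop = FALSE], fs$sample_id, fs$library,
                      dedup_applied = TRUE)
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Retain fragments within a size range
#'
#' Keeps records with `lo <= length <= hi` (both inclusive). The analysis
#' focuses on mononucleosomal fragments of 100-220 bp.
#'
#' @param fs A [fragment_set()].
#' @param lo,hi Inclusive length bounds in bp.
#' @return Filtered [fragment_set()].
#' @export
filter_size_range <- function(fs, lo = 100L, hi = 220L) {
  stopifnot(inherits(fs, "fragment_set"))
  if (lo > hi) stop("lo must not exceed hi")
  keep <- fs$records$length >= lo & fs$records$length <= hi
  fragment_set(fs$records[keep, , drop = FALSE], fs$sample_id, fs$library,
               dedup_applied = fs$dedup_applied)
}

#' Assign fragments to genome windows
#'
#' Each fragment is assigned to exactly one window: the one containing its
#' midpoint `floor((start + end) / 2)`. The mapping conserves fragments (the
#' per-window index lists partition the record indices).
#'
#' @param fs A [fragment_set()].
#' @param grid A [window_grid()].
#' @return Named list mapping window id to integer record indices; windows
#'   with no fragments are omitted.
#' @export
assign_to_windows <- function(fs, grid) {
  stopifnot(inherits(fs, "fragment_set"))
  idx <- window_index(fs$records$chrom, fs$records$start, fs$records$end, grid)
  split(seq_len(nrow(fs$records)), grid$windows$id[idx])
}
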