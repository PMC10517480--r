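# Fixture builders and independent oracles shared across the test files.
# All fixtures are generated in code; oracles are deliberately naive
# (brute-force loops, closed forms) and never call the code paths they check.

toy_layout <- function(chr1 = 1e5, chr2 = 1e5) {
  genome_layout(c(chr1 = chr1, chr2 = chr2))
}

# fragment set with given lengths, each fragment's midpoint inside the given
# window (0-based window index on chr1 of `grid`)
fs_from_lengths <- function(lengths, grid = NULL, window = 0L, chrom = "chr1",
                            sample_id = "S1", library = "INPUT") {
  wbp <- if (is.null(grid)) 10000L else grid$window_bp
  start <- window * wbp + seq_along(lengths) - 1L
  fragment_set(
    data.frame(chrom = rep(chrom, length(lengths)), start = start,
               end = start + lengths,
               barcode = sprintf("B%03d", seq_along(lengths))),
    sample_id = sample_id, library = library
  )
}

# sample_summary built through the real summarize path from synthetic
# fragments: per-window IP/Input short (120 bp) and long (180 bp) counts
toy_summary <- function(grid, short_ip, long_ip, short_in, long_in,
                        sample_id = "S1", group = "healthy") {
  stopifnot(length(short_ip) == grid$n_windows)
  build_lib <- function(short, long, library) {
    recs <- do.call(rbind, lapply(seq_len(grid$n_windows), function(w) {
      n <- short[w] + long[w]
      if (n == 0) return(NULL)
      len <- rep(c(120L, 180L), c(short[w], long[w]))
      start <- grid$windows$start[w] + seq_len(n)
      data.frame(chrom = grid$windows$chrom[w], start = start,
                 end = start + len,
                 barcode = sprintf("%s-%d-%d", library, w, seq_len(n)))
    }))
    if (is.null(recs))
      recs <- data.frame(chrom = character(), start = integer(),
                         end = integer(), barcode = character())
    fragment_set(recs, sample_id, library, dedup_applied = TRUE)
  }
  summarize_sample(build_lib(short_in, long_in, "INPUT"),
                   build_lib(short_ip, long_ip, "IP"),
                   grid, group = group)
}

# small simulated cohort for integration-style tests
small_cohort_config <- function(seed = 11L, ...) {
  defaults <- list(layout = genome_layout(c(chr1 = 5e5, chr2 = 5e5)),
                   n_input = 20000L, n_hypo = 5L, n_hyper = 5L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# --- independent oracles ---------------------------------------------------

# Benjamini-Hochberg step-up by direct definition
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  padj_sorted <- numeric(n)
  ps <- p[ord]
  for (i in seq_len(n)) {
    padj_sorted[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- padj_sorted
  out
}

# AUC by O(n^2) pair counting: P(score_cancer < score_healthy) + 0.5 ties
auc_paircount <- function(scores, labels) {
  sc <- scores[labels == "cancer"]
  sh <- scores[labels == "healthy"]
  tot <- 0
  for (c in sc) for (h in sh) tot <- tot + (c < h) + 0.5 * (c == h)
  tot / (length(sc) * length(sh))
}

# Pearson correlation from the definitional formula
pearson_formula <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# median-of-ratios size factors by direct definition (loops, no matrix ops)
size_factors_bruteforce <- function(counts) {
  all_pos <- apply(counts, 1, function(y) all(y > 0))
  ref <- apply(counts[all_pos, , drop = FALSE], 1,
               function(y) prod(y)^(1 / length(y)))
  sapply(seq_len(ncol(counts)), function(j)
    median(counts[all_pos, j] / ref))
}

# mean of an integer-floored truncated normal on [lo, hi] by summation
trunc_len_mean <- function(mu, sd, lo, hi) {
  k <- lo:hi
  pk <- pnorm(k + 1, mu, sd) - pnorm(k, mu, sd)
  sum(k * pk) / sum(pk)
}

# SAM text for paired-end fixtures; returns a BAM path
write_fixture_bam <- function(pairs, dir = NULL) {
  if (is.null(dir)) { dir <- tempfile("bamfix"); dir.create(dir) }
  # pairs: data.frame qname, chrom, pos1, pos2, isize, flag1, flag2,
  #        mapq1, mapq2 (1-based positions, 10M read length placeholder)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              "@SQ\tSN:chr1\tLN:100000", "@SQ\tSN:chr2\tLN:100000")
  recs <- character(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    mate <- if (is.na(p$pos2)) p$pos1 else p$pos2
    recs <- c(recs,
      sprintf("%s\t%d\t%s\t%d\t%d\t10M\t=\t%d\t%d\tAAAAAAAAAA\t*",
              p$qname, p$flag1, p$chrom, p$pos1, p$mapq1, mate, p$isize),
      if (!is.na(p$flag2))
        sprintf("%s\t%d\t%s\t%d\t%d\t10M\t=\t%d\t%d\tAAAAAAAAAA\t*",
                p$qname, p$flag2, p$chrom, p$pos2, p$mapq2, p$pos1, -p$isize))
  }
  sam <- file.path(dir, "fixture.sam")
  writeLines(c(header, recs), sam)
  Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE,
                   indexDestination = FALSE)
}

# standard proper pair rows for write_fixture_bam
proper_pair <- function(qname, chrom, start1, insert, mapq = 60,
                        proper = TRUE) {
  base1 <- 99L; base2 <- 147L  # paired, proper, mate reverse / reverse
  if (!proper) { base1 <- base1 - 2L; base2 <- base2 - 2L }
  data.frame(qname = qname, chrom = chrom, pos1 = start1,
             pos2 = start1 + insert - 10L, isize = insert,
             flag1 = base1, flag2 = base2, mapq1 = mapq, mapq2 = mapq)
}
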