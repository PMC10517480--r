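toy_cm <- function(counts, groups, grid = NULL) {
  # count_matrix built directly for statistical unit tests
  if (is.null(grid)) grid <- window_grid(toy_layout(nrow(counts) * 1e4, 1e4),
                                         10000L)
  ids <- paste0("S", seq_len(ncol(counts)))
  dimnames(counts) <- list(grid$windows$id[seq_len(nrow(counts))], ids)
  structure(list(counts = counts,
                 windows = grid$windows[seq_len(nrow(counts)), ],
                 groups = stats::setNames(groups, ids)),
            class = "count_matrix")
}

test_that("count matrices conserve per-sample fragment totals", {
  grid <- window_grid(toy_layout(), 10000L)
  # two fragments in the fourth window (0-based index 3)
  fs <- fragment_set(data.frame(chrom = "chr1",
                                start = c(31000L, 32000L, 35000L),
                                end = c(31167L, 32140L, 35180L),
                                barcode = c("A", "B", "C")),
                     "S1", "IP", dedup_applied = TRUE)
  cm <- build_count_matrix(list(fs), grid, groups = "healthy")
  expect_equal(unname(cm$counts["chr1:30000-40000", "S1"]), 3L)
  expect_equal(sum(cm$counts), 3)

  empty <- fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer()), "S2", "IP",
                        dedup_applied = TRUE)
  cm2 <- build_count_matrix(list(fs, empty), grid,
                            groups = c("healthy", "cancer"))
  expect_equal(unname(colSums(cm2$counts)), c(3, 0))

  expect_error(build_count_matrix(list(fs, fs), grid,
                                  groups = c("healthy", "cancer")),
               "duplicate sample ids")

  # from summaries: column sums equal retained IP fragments
  cfg <- small_cohort_config(n_input = 5000L)
  cs <- cohort_summaries(cfg)
  cm3 <- build_count_matrix(cs$summaries, cs$landscape$grid)
  expect_equal(unname(colSums(cm3$counts)),
               unname(sapply(cs$summaries, `[[`, "n_ip")))
})

test_that("the mean-count filter applies the strict less-than-10 rule", {
  counts <- rbind(rep(9L, 4), rep(10L, 4), c(0L, 0L, 40L, 0L))
  cm <- toy_cm(counts, c("healthy", "healthy", "cancer", "cancer"))
  kept <- filter_low_count_windows(cm, 10)
  expect_equal(nrow(kept$counts), 2)  # mean 9 removed; mean 10 kept
  expect_false(rownames(cm$counts)[1] %in% rownames(kept$counts))
  expect_equal(filter_low_count_windows(cm, 0)$counts, cm$counts)
})

test_that("size factors match the median-of-ratios definition", {
  ident <- toy_cm(matrix(c(5L, 9L, 5L, 9L, 5L, 9L), nrow = 2),
                  rep(c("healthy", "cancer"), c(2, 1)))
  expect_equal(unname(estimate_size_factors(ident)), c(1, 1, 1))

  # second column doubles the first: s = {1/sqrt(2), sqrt(2)}
  doubling <- toy_cm(cbind(c(10L, 30L), c(20L, 60L)),
                     c("healthy", "cancer"))
  expect_equal(unname(estimate_size_factors(doubling)),
               c(0.7071, 1.4142), tolerance = 1e-4)

  single <- toy_cm(matrix(c(5L, 7L), ncol = 1), "healthy")
  expect_equal(unname(estimate_size_factors(single)), 1)

  # crafted 4x6 matrix vs the brute-force oracle
  set.seed(15)
  m46 <- matrix(rpois(24, 50) + 1L, nrow = 4)
  cm46 <- toy_cm(m46, rep(c("healthy", "cancer"), each = 3))
  expect_equal(unname(estimate_size_factors(cm46)),
               size_factors_bruteforce(m46))

  # zero in every window -> error unless the pseudo-reference is allowed
  withzero <- toy_cm(cbind(c(0L, 5L), c(4L, 0L)), c("healthy", "cancer"))
  expect_error(estimate_size_factors(withzero), "all-positive")
  sf <- estimate_size_factors(withzero, fallback_pseudo = TRUE)
  expect_true(all(sf > 0))
})

test_that("the NB Wald test is null on identical groups and signs effects", {
  counts <- matrix(rep(c(50L, 80L), each = 6), nrow = 2, byrow = TRUE)
  cm <- toy_cm(counts, rep(c("healthy", "cancer"), 3))
  res <- nb_window_test(cm, estimate_size_factors(cm))
  expect_equal(res$log2fc, c(0, 0))
  expect_true(all(res$p > 0.99))

  # swapping labels negates log2fc and leaves p unchanged
  set.seed(16)
  counts2 <- matrix(rnbinom(120, mu = 60, size = 10), nrow = 20)
  g <- rep(c("healthy", "cancer"), each = 3)
  cmA <- toy_cm(counts2, g)
  cmB <- toy_cm(counts2, rev(g))
  resA <- nb_window_test(cmA, estimate_size_factors(cmA))
  resB <- nb_window_test(cmB, estimate_size_factors(cmB))
  expect_equal(resA$log2fc, -resB$log2fc, tolerance = 1e-10)
  expect_equal(resA$p, resB$p, tolerance = 1e-8)
})

test_that("planted four-fold windows are recovered near log2fc = 2", {
  set.seed(17)
  n_win <- 200
  counts <- rbind(
    cbind(matrix(rnbinom(3 * n_win, mu = 40, size = 20), ncol = 3),
          matrix(rnbinom(3 * n_win, mu = 160, size = 20), ncol = 3)))
  cm <- toy_cm(counts, rep(c("healthy", "cancer"), each = 3),
               grid = window_grid(genome_layout(c(chr1 = n_win * 1e4)), 1e4))
  res <- nb_window_test(cm, rep(1, 6))
  expect_lt(abs(median(res$log2fc) - 2), 0.3)
  expect_true(all(bh_adjust(res$p) < 0.05))
})

test_that("large-count, low-dispersion p-values track the normal-limit oracle", {
  set.seed(18)
  n_win <- 60
  mu_h <- 2000; mu_c <- 2100
  # 10 samples per group so the moment dispersion estimate is itself close
  # to its zero limit on Poisson data
  counts <- cbind(matrix(rpois(10 * n_win, mu_h), ncol = 10),
                  matrix(rpois(10 * n_win, mu_c), ncol = 10))
  cm <- toy_cm(counts, rep(c("healthy", "cancer"), each = 10),
               grid = window_grid(genome_layout(c(chr1 = n_win * 1e4)), 1e4))
  res <- nb_window_test(cm, rep(1, 20))
  # oracle: Wald on log rate ratio of pooled Poisson counts
  t_h <- rowSums(counts[, 1:10]); t_c <- rowSums(counts[, 11:20])
  z <- log(t_c / t_h) / sqrt(1 / t_c + 1 / t_h)
  p_oracle <- 2 * pnorm(-abs(z))
  # compare where both calls are clearly nonnull so -log10 is stable
  comp <- p_oracle < 0.01 & p_oracle > 1e-12 & res$p > 1e-15
  expect_gt(sum(comp), 10)
  ratio <- -log10(res$p[comp]) / -log10(p_oracle[comp])
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  for (i in 1:20) {
    p <- round(runif(sample(1:40, 1)), sample(1:3, 1))  # induce ties
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
  # monotone and never below the raw p
  p <- sort(runif(50))
  padj <- bh_adjust(p)
  expect_true(all(diff(padj) >= 0))
  expect_true(all(padj >= p))
})

test_that("DMR classes follow the padj and fold-change thresholds", {
  res <- data.frame(id = c("a", "b", "c", "d"),
                    chrom = "chr1", start = 0, end = 1,
                    baseMean = 50, log2fc = c(1.5, -1.2, 3.0, 0.2),
                    dispersion = 0.01,
                    p = c(0.001, 0.001, 0.08, 0.001))
  out <- classify_dmrs(res, alpha = 0.05, lfc = 1)
  expect_equal(out$class, c("HYPER", "HYPO", "NONE", "NONE"))
  # raw-p mode: the weaker window becomes callable only through raw p
  res2 <- res; res2$p <- c(0.04, 0.04, 0.04, 0.04)
  out2 <- classify_dmrs(res2, use_padj = FALSE)
  expect_equal(out2$class, c("HYPER", "HYPO", "HYPER", "NONE"))
})

test_that("single-sample groups yield fold changes but no p-values", {
  counts <- matrix(c(10L, 40L, 20L, 80L), nrow = 2)
  cm <- toy_cm(counts, c("healthy", "cancer"))
  res <- nb_window_test(cm, c(1, 1))
  expect_true(all(is.na(res$p)))
  expect_equal(res$log2fc, log2((counts[, 2] + 0.5) / (counts[, 1] + 0.5)))
  expect_error(nb_window_test(toy_cm(counts, c("healthy", "healthy")),
                              c(1, 1)),
               "empty group: cancer")
})
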