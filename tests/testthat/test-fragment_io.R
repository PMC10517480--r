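test_that("fragment tables read back records verbatim", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t267\tAAGGCTTA",
               "chr1\t500\t640\tCCTTGGAA",
               "chr2\t0\t180\tAAGGCTTA"), path)
  fs <- read_fragment_table(path, "S1", "INPUT")
  expect_equal(n_fragments(fs), 3)
  expect_equal(fs$records$barcode[1], "AAGGCTTA")
  expect_equal(fs$records$length, c(167L, 140L, 180L))
  expect_false(fs$dedup_applied)

  # missing barcode column -> empty barcodes
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t267", "chr1\t500\t640"), path2)
  fs2 <- read_fragment_table(path2, "S1", "IP")
  expect_equal(fs2$records$barcode, c("", ""))
})

test_that("malformed fragment lines raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t267\tA", "chr1\t500\t500\tB"), path)
  expect_error(read_fragment_table(path, "S1"), "line 2.*end <= start")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\tabc\t267\tA"), path2)
  expect_error(read_fragment_table(path2, "S1"), "line 1")
})

test_that("fragment tables round-trip through write and read", {
  fs <- fs_from_lengths(c(167L, 140L, 180L, 100L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_table(fs, path)
  back <- read_fragment_table(path, fs$sample_id, fs$library)
  expect_equal(back$records, fs$records)
})

test_that("deduplication keeps the first record per (chrom,start,end,barcode)", {
  fs <- fragment_set(data.frame(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(1000L, 1000L, 1000L), end = c(1167L, 1167L, 1167L),
    barcode = c("AAGG", "AAGG", "CCTT")), "S1", "INPUT")
  dd <- deduplicate(fs)
  expect_equal(n_fragments(dd), 2)
  expect_true(dd$dedup_applied)
  expect_equal(attr(dd, "n_duplicates"), 1)
  expect_equal(dd$records$barcode, c("AAGG", "CCTT"))
})

test_that("deduplication is idempotent and a no-op on distinct keys", {
  empty <- fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer()), "S1", "INPUT")
  expect_equal(n_fragments(deduplicate(empty)), 0)

  set.seed(42)
  for (i in 1:5) {
    n <- 50
    fs <- fragment_set(data.frame(
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      start = s <- sample.int(1000, n, TRUE),
      end = s + sample.int(200, n, TRUE),
      barcode = sample(c("A", "B"), n, TRUE)), "S1", "INPUT")
    once <- deduplicate(fs)
    twice <- deduplicate(once)
    expect_equal(twice$records, once$records)
  }

  distinct <- fs_from_lengths(c(101L, 102L, 103L))
  expect_equal(deduplicate(distinct)$records, distinct$records)
})

test_that("size filtering is inclusive at both bounds", {
  fs <- fs_from_lengths(c(99L, 100L, 220L, 221L))
  kept <- filter_size_range(fs, 100L, 220L)
  expect_equal(sort(kept$records$length), c(100L, 220L))

  expect_equal(n_fragments(filter_size_range(fs_from_lengths(integer(0)))), 0)
  one <- filter_size_range(fs_from_lengths(c(166L, 167L, 168L)), 167L, 167L)
  expect_equal(one$records$length, 167L)
  expect_error(filter_size_range(fs, 200L, 100L), "lo must not exceed hi")
  # wide bounds are the identity
  expect_equal(filter_size_range(fs, 1L, .Machine$integer.max)$records,
               fs$records)
})

test_that("window assignment follows the midpoint rule and conserves fragments", {
  grid <- window_grid(toy_layout(), 10000L)
  fs <- fragment_set(data.frame(chrom = "chr1", start = 9995L, end = 10162L,
                                barcode = "A"), "S1", "INPUT")
  # midpoint floor((9995+10162)/2) = 10078 -> second 10-kb window
  m <- assign_to_windows(fs, grid)
  expect_equal(names(m), "chr1:10000-20000")

  inside <- fragment_set(data.frame(chrom = "chr1", start = 100L, end = 267L,
                                    barcode = "A"), "S1", "INPUT")
  expect_equal(names(assign_to_windows(inside, grid)), "chr1:0-10000")

  two <- fragment_set(data.frame(chrom = c("chr1", "chr2"),
                                 start = c(0L, 15000L), end = c(150L, 15180L),
                                 barcode = c("A", "B")), "S1", "INPUT")
  m2 <- assign_to_windows(two, grid)
  expect_equal(sum(lengths(m2)), 2)
  expect_equal(length(m2), 2)

  # conservation over a larger random set
  set.seed(7)
  n <- 500
  fsr <- fragment_set(data.frame(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = s <- sample.int(90000, n, TRUE) - 1L,
    end = s + sample.int(220, n, TRUE),
    barcode = as.character(seq_len(n))), "S1", "INPUT")
  expect_equal(sum(lengths(assign_to_windows(fsr, grid))), n)

  alien <- fragment_set(data.frame(chrom = "chrX", start = 0L, end = 100L,
                                   barcode = "A"), "S1", "INPUT")
  expect_error(assign_to_windows(alien, grid), "chrX")
})

test_that("paired alignments yield filtered fragments with drop accounting", {
  skip_if_not_installed("Rsamtools")
  pairs <- rbind(
    proper_pair("AAGGCTTA:r1", "chr1", 1001L, 167L),          # kept, len 167
    proper_pair("CCTTGGAA:r2", "chr1", 2001L, 15L),           # insert < 20
    proper_pair("GGAACCTT:r3", "chr1", 3001L, 150L, proper = FALSE),
    proper_pair("TTCCAAGG:r4", "chr2", 4001L, 180L, mapq = 5L) # low mapq
  )
  bam <- write_fixture_bam(pairs)
  fs <- fragments_from_paired_alignments(bam, "S1", "INPUT")
  expect_equal(n_fragments(fs), 1)
  expect_equal(fs$records$length, 167L)
  expect_equal(fs$records$start, 1000L)  # 0-based from 1-based BAM pos
  expect_equal(fs$records$barcode, "AAGGCTTA")
  dropped <- attr(fs, "dropped")
  expect_equal(unname(dropped["short_insert"]), 1L)
  expect_equal(unname(dropped["not_proper"]), 1L)
  expect_equal(unname(dropped["low_mapq"]), 1L)
})

test_that("orphan reads are skipped with a warning", {
  skip_if_not_installed("Rsamtools")
  pairs <- proper_pair("AAGG:r1", "chr1", 1001L, 167L)
  orphan <- data.frame(qname = "CCTT:solo", chrom = "chr1", pos1 = 5001L,
                       pos2 = NA, isize = 167L, flag1 = 99L, flag2 = NA,
                       mapq1 = 60L, mapq2 = NA)
  bam <- write_fixture_bam(rbind(pairs, orphan))
  expect_warning(fs <- fragments_from_paired_alignments(bam, "S1", "INPUT"),
                 "orphan")
  expect_equal(n_fragments(fs), 1)
  expect_equal(unname(attr(fs, "dropped")["orphan"]), 1L)
})

test_that("alignment extraction round-trips through fragment tables", {
  skip_if_not_installed("Rsamtools")
  pairs <- rbind(proper_pair("AAGG:r1", "chr1", 1001L, 167L),
                 proper_pair("CCTT:r2", "chr2", 2001L, 140L))
  bam <- write_fixture_bam(pairs)
  fs <- fragments_from_paired_alignments(bam, "S1", "IP")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_table(fs, path)
  back <- read_fragment_table(path, "S1", "IP")
  expect_equal(back$records, fs$records)
})
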