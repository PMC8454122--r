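# Read counting, FRiP, binned counts and RPM signal extraction on
# hand-enumerable BAM fixtures.

cs1 <- c(chrT = 100000L)

test_that("scan_bam counts primary mapped reads under the configured filters", {
  reads <- data.frame(chrom = "chrT",
                      start = seq(1000L, by = 1000L, length.out = 10L),
                      width = 50L, strand = "+",
                      mapq = c(rep(60L, 6), rep(10L, 4)),
                      stringsAsFactors = FALSE)
  bam <- write_test_bam(reads, cs1, tmp_path(".bam"), secondary = 2L)
  expect_equal(scan_bam(bam, mapq_min = 0)$mapped_reads, 10L)
  expect_equal(scan_bam(bam, mapq_min = 30)$mapped_reads, 6L)
  expect_equal(scan_bam(bam, mapq_min = 0)$read_length, 50L)
  expect_false(scan_bam(bam)$paired)

  reads$dup <- c(TRUE, rep(FALSE, 9))
  bam2 <- write_test_bam(reads, cs1, tmp_path(".bam"))
  expect_equal(scan_bam(bam2, 0, dedup = TRUE)$mapped_reads, 9L)
  expect_equal(scan_bam(bam2, 0, dedup = FALSE)$mapped_reads, 10L)
})

test_that("empty and unmapped-only BAMs scan to zero reads without error", {
  empty <- write_test_bam(data.frame(), cs1, tmp_path(".bam"))
  expect_equal(scan_bam(empty)$mapped_reads, 0L)
  unm <- write_test_bam(data.frame(), cs1, tmp_path(".bam"), unmapped = 3L)
  expect_equal(scan_bam(unm)$mapped_reads, 0L)
})

test_that("FRiP is the exact fraction of reads overlapping peaks", {
  # 10 reads, 3 land in the peak (one by a single base)
  reads <- data.frame(chrom = "chrT",
                      start = c(2000L, 2100L, 2249L, seq(10000L, by = 2000L,
                                                         length.out = 7L)),
                      width = 50L, strand = "+", stringsAsFactors = FALSE)
  bam <- write_test_bam(reads, cs1, tmp_path(".bam"))
  sa <- scan_bam(bam, 0, FALSE)
  peak <- make_peak_set(data.frame(chrom = "chrT", start = 1900, end = 2250),
                        "pk")
  expect_equal(frip(sa, peak), 0.3)

  all_in <- make_peak_set(data.frame(chrom = "chrT", start = 0, end = 100000),
                          "all")
  expect_equal(frip(sa, all_in), 1.0)

  none <- make_peak_set(data.frame(chrom = character(), start = integer(),
                                   end = integer()), "none")
  expect_equal(frip(sa, none), 0.0)

  empty <- scan_bam(write_test_bam(data.frame(), cs1, tmp_path(".bam")))
  expect_error(frip(empty, peak), "no mapped reads")
})

test_that("FRiP ignores record order and splitting a peak into touching halves", {
  set.seed(31)
  spec <- fixture_spec(chrom_sizes = c(chrSim = 200000L),
                       true_peaks = data.frame(chrom = "chrSim",
                                               start = c(20000, 60000),
                                               end = c(20400, 60400)),
                       n_fragments = 800L, seed = 31L)
  sim <- simulate_sample(spec, tmp_path(".bam"))
  sa <- scan_bam(sim$bam, 0, FALSE)
  pk <- make_peak_set(spec$true_peaks[, 1:3], "p")
  base <- frip(sa, pk)
  shuf <- pk
  shuf$records <- shuf$records[c(2, 1), ]
  expect_equal(frip(sa, shuf), base)
  split <- make_peak_set(data.frame(chrom = "chrSim",
                                    start = c(20000, 20200, 60000),
                                    end = c(20200, 20400, 60400)), "p2")
  expect_equal(frip(sa, split), base)
})

test_that("binned counts assign reads by 5' position into half-open bins", {
  reads <- data.frame(chrom = "chrT",
                      start = c(15000L, 10000L, 9999L, 25000L),
                      width = 50L,
                      strand = c("+", "+", "+", "-"),
                      stringsAsFactors = FALSE)
  # minus-strand read at [25000,25050): 5' end at 25049
  bam <- write_test_bam(reads, cs1, tmp_path(".bam"))
  bc <- binned_counts(scan_bam(bam, 0, FALSE), cs1, 10000L)
  expect_equal(bc$counts, c(1L, 2L, 1L, rep(0L, 7)))
  expect_equal(sum(bc$counts), scan_bam(bam, 0, FALSE)$mapped_reads)
})

test_that("count correlation follows the Pearson formula and its symmetries", {
  mk <- function(counts) structure(list(sample_id = "x",
                                        bins = tile_genome(cs1, 10000L),
                                        counts = counts),
                                   class = "binned_counts")
  a <- mk(c(1L, 2L, 3L, rep(0L, 7)))
  b <- mk(c(2L, 4L, 6L, rep(0L, 7)))
  expect_equal(count_correlation(a, b, "raw"), 1.0)
  expect_equal(count_correlation(a, a, "raw"), 1.0)

  set.seed(5)
  x <- mk(rpois(10, 4))
  y <- mk(rpois(10, 4))
  expect_equal(count_correlation(x, y, "log1p"),
               stats::cor(log1p(x$counts), log1p(y$counts)))
  expect_equal(count_correlation(x, y), count_correlation(y, x))

  z <- mk(rep(3L, 10))
  expect_error(count_correlation(x, z), "zero variance")
})

test_that("signal matrix computes RPM bin means from fragment pileup", {
  # one single-end plus read extended to fragment length 200 covers
  # [1000, 1200): exactly bin 1 of the window [1000, 2000) at 5 bins x 200
  reads <- data.frame(chrom = "chrT", start = 1000L, width = 50L,
                      strand = "+", stringsAsFactors = FALSE)
  bam <- write_test_bam(reads, cs1, tmp_path(".bam"))
  sa <- scan_bam(bam, 0, FALSE)
  win <- data.frame(chrom = "chrT", start = 1000L, end = 2000L)
  sm <- signal_matrix(list(sa), win, n_bins = 5L, fragment_length = 200L,
                      chrom_sizes = cs1)
  scale <- 1e6 / sa$mapped_reads
  expect_equal(as.numeric(sm$values[1, 1, ]), c(scale, 0, 0, 0, 0))
  expect_equal(sm$normalization, "RPM")

  far <- data.frame(chrom = "chrT", start = 50000L, end = 51000L)
  sm0 <- signal_matrix(list(sa), far, n_bins = 5L, fragment_length = 200L,
                       chrom_sizes = cs1)
  expect_true(all(sm0$values == 0))
})

test_that("duplicating every read leaves RPM signal and FRiP unchanged", {
  set.seed(17)
  spec <- fixture_spec(chrom_sizes = c(chrSim = 150000L),
                       true_peaks = data.frame(chrom = "chrSim",
                                               start = 50000, end = 50400),
                       n_fragments = 400L, paired = FALSE, seed = 17L)
  sim <- simulate_sample(spec, tmp_path(".bam"))
  reads <- cnrqc:::load_reads(sim$bam, 0, FALSE)
  doubled <- rbind(reads, reads)
  bam2 <- write_test_bam(
    data.frame(chrom = doubled$chrom, start = doubled$start,
               width = doubled$end - doubled$start, strand = doubled$strand),
    spec$chrom_sizes, tmp_path(".bam"))
  sa1 <- scan_bam(sim$bam, 0, FALSE, sample_id = "x")
  sa2 <- scan_bam(bam2, 0, FALSE, sample_id = "x")
  expect_equal(sa2$mapped_reads, 2L * sa1$mapped_reads)
  pk <- make_peak_set(spec$true_peaks[, 1:3], "p")
  expect_equal(frip(sa2, pk), frip(sa1, pk))
  win <- resize_fixed_width(spec$true_peaks, 2000)
  sm1 <- signal_matrix(list(sa1), win, 50, 180, spec$chrom_sizes)
  sm2 <- signal_matrix(list(sa2), win, 50, 180, spec$chrom_sizes)
  expect_equal(sm2$values, sm1$values)
})

test_that("signal mass over a covering window conserves fragment bases", {
  reads <- data.frame(chrom = "chrT", start = c(10000L, 12000L, 13500L),
                      width = 50L, strand = c("+", "+", "-"),
                      stringsAsFactors = FALSE)
  bam <- write_test_bam(reads, cs1, tmp_path(".bam"))
  sa <- scan_bam(bam, 0, FALSE)
  win <- data.frame(chrom = "chrT", start = 8000L, end = 16000L)
  sm <- signal_matrix(list(sa), win, n_bins = 80L, fragment_length = 150L,
                      chrom_sizes = cs1)
  # 3 fragments x 150 bases, scaled by 1e6/3 reads; bin means x bin width
  expect_equal(sum(sm$values[1, 1, ]) * sm$bin_width, 3 * 150 * 1e6 / 3)
})

test_that("regions past the chromosome end warn and zero-fill", {
  reads <- data.frame(chrom = "chrT", start = 99000L, width = 50L,
                      strand = "+", stringsAsFactors = FALSE)
  bam <- write_test_bam(reads, cs1, tmp_path(".bam"))
  sa <- scan_bam(bam, 0, FALSE)
  win <- data.frame(chrom = "chrT", start = 99500L, end = 100500L)
  expect_warning(sm <- signal_matrix(list(sa), win, n_bins = 10L,
                                     fragment_length = 100L,
                                     chrom_sizes = cs1),
                 "past chromosome ends")
  expect_equal(dim(sm$values), c(1L, 1L, 10L))
})
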