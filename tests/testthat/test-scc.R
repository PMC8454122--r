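# Strand cross-correlation: position vectors, the shift curve against a
# brute-force Pearson oracle, fragment-length estimation and phantom-peak
# artifact flagging.

test_that("strand position vectors tally 5' ends per strand", {
  reads <- data.frame(chrom = "chrT",
                      start = c(100L, 230L),
                      end = c(150L, 280L),
                      strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  region <- list(chrom = "chrT", start = 50L, end = 350L)
  v <- strand_position_vectors(reads, region)
  expect_equal(which(v$plus == 1), 100 - 50 + 1)
  expect_equal(which(v$minus == 1), 279 - 50 + 1)
  expect_equal(sum(v$plus) + sum(v$minus), 2)

  none <- strand_position_vectors(reads[0, ], region)
  expect_equal(sum(none$plus) + sum(none$minus), 0)
  expect_equal(length(none$plus), 300)
})

test_that("scc_curve equals direct per-shift Pearson on random vectors", {
  set.seed(42)
  for (rep in 1:40) {
    L <- sample(20:200, 1)
    plus <- rpois(L, 0.4)
    minus <- rpois(L, 0.4)
    ms <- sample.int(L - 1L, 1)
    expect_equal(scc_curve(plus, minus, ms), brute_scc(plus, minus, ms),
                 tolerance = 1e-12)
  }
})

test_that("scc_curve handles identity, translation and degenerate input", {
  set.seed(9)
  x <- rpois(400, 0.5)
  expect_equal(scc_curve(x, x, 0)[1], 1.0)

  d <- 37L
  shifted <- c(numeric(d), x[seq_len(400 - d)])
  curve <- scc_curve(x, shifted, 100)
  expect_equal(which.max(curve) - 1L, d)
  expect_equal(max(curve), 1.0)

  expect_equal(scc_curve(x, numeric(400), 50), numeric(51))
  expect_error(scc_curve(x, numeric(400), 400), "max_shift")
  expect_error(scc_curve(x, numeric(399), 10), "differ in length")
})

test_that("the curve is invariant to translating both strands together", {
  set.seed(13)
  core_p <- rpois(200, 0.6)
  core_m <- rpois(200, 0.6)
  embed <- function(core, off, L = 400L) {
    v <- numeric(L)
    v[off + seq_along(core)] <- core
    v
  }
  # same mass placed at two offsets; populated span stays clear of both
  # vector ends for every tested shift, so the curves agree exactly
  expect_equal(scc_curve(embed(core_p, 60L), embed(core_m, 60L), 50),
               scc_curve(embed(core_p, 100L), embed(core_m, 100L), 50),
               tolerance = 1e-12)
})

test_that("fragment-length estimation excludes the read-length phantom window", {
  curve <- numeric(300)
  curve[50] <- 0.95   # phantom at read length 50 (shift 49)
  curve[180] <- 0.6   # true fragment peak at length 180
  expect_equal(estimate_fragment_length(curve, read_length = 50L,
                                        exclusion_halfwidth = 10L), 180L)
  # without exclusion the phantom wins
  expect_equal(estimate_fragment_length(curve, read_length = NA,
                                        exclusion_halfwidth = 0L), 50L)
  # flat curve: tie broken toward the largest shift
  expect_equal(estimate_fragment_length(numeric(120), 50L, 10L), 120L)
  expect_error(estimate_fragment_length(numeric(15), read_length = 8L,
                                        exclusion_halfwidth = 20L),
               "exclusion window")
})

test_that("average_scc weights per-region curves and skips empty regions", {
  regions <- data.frame(chrom = "chrT", start = c(0L, 500L, 1000L),
                        end = c(400L, 900L, 1400L))
  rs <- structure(list(
    regions = regions, shifts = 0:99,
    correlations = rbind(seq(0, 0.99, by = 0.01),
                         rep(0.5, 100),
                         rep(0.9, 100)),
    read_counts = c(10L, 30L, 0L),
    read_length = 50L, sample_id = "s"), class = "region_scc")
  avg_u <- average_scc(rs, "uniform")
  expect_equal(avg_u$correlations,
               (seq(0, 0.99, by = 0.01) + 0.5) / 2)
  expect_equal(avg_u$n_regions, 2L)
  avg_w <- average_scc(rs, "by_read_count")
  expect_equal(avg_w$correlations,
               (10 * seq(0, 0.99, by = 0.01) + 30 * 0.5) / 40)

  one <- rs
  one$read_counts <- c(5L, 0L, 0L)
  expect_equal(average_scc(one)$correlations, seq(0, 0.99, by = 0.01))

  none <- rs
  none$read_counts <- c(0L, 0L, 0L)
  expect_error(average_scc(none), "no region contains reads")
})

test_that("read-length-periodic regions are flagged, structured ones are not", {
  cs <- c(chrT = 20000L)
  rl <- 50L
  # artifact: every read duplicated on both strands over the same span,
  # so plus and minus 5' profiles coincide after a shift of rl - 1
  pos <- seq(5000L, 5400L, by = 20L)
  art <- data.frame(chrom = "chrT", start = rep(pos, 2), width = rl,
                    strand = rep(c("+", "-"), each = length(pos)),
                    stringsAsFactors = FALSE)
  # proper library: plus at s, minus at s + 180 - rl
  frag <- seq(8000L, 8400L, by = 20L)
  good <- data.frame(chrom = "chrT",
                     start = c(frag, frag + 180L - rl),
                     width = rl,
                     strand = rep(c("+", "-"), each = length(frag)),
                     stringsAsFactors = FALSE)
  bam <- write_test_bam(rbind(art, good), cs, tmp_path(".bam"))
  sa <- scan_bam(bam, 0, FALSE)
  regions <- data.frame(chrom = "chrT", start = c(4800L, 7800L),
                        end = c(5800L, 8800L))
  rs <- region_scc(sa, regions, max_shift = 400L)
  flags <- flag_artifact_regions(rs, fragment_length = 180L,
                                 read_length = rl, threshold = 0.9)
  expect_true(flags$artifact_flag[1])
  expect_false(flags$artifact_flag[2])
  expect_equal(flags$corr_at_read_length[1], 1.0)

  # raising the threshold never flags more regions
  prev <- Inf
  for (th in c(0.5, 0.7, 0.9, 1.0)) {
    n <- sum(flag_artifact_regions(rs, 180L, rl, th)$artifact_flag)
    expect_lte(n, prev)
    prev <- n
  }
  expect_equal(sum(flag_artifact_regions(rs, 180L, rl, 1.0)$artifact_flag), 0L)
})

test_that("region_scc recovers the spacing of a constructed two-strand comb", {
  cs <- c(chrT = 10000L)
  s <- seq(2000L, 2900L, by = 30L)
  d <- 120L
  reads <- data.frame(chrom = "chrT", start = c(s, s + d - 49L), width = 50L,
                      strand = rep(c("+", "-"), each = length(s)),
                      stringsAsFactors = FALSE)
  # minus 5' ends at start + 49, i.e. s + d: 5'-to-5' span of d + 1
  bam <- write_test_bam(reads, cs, tmp_path(".bam"))
  rs <- region_scc(scan_bam(bam, 0, FALSE),
                   data.frame(chrom = "chrT", start = 1800L, end = 3300L),
                   max_shift = 300L)
  prof <- average_scc(rs)
  expect_equal(prof$fragment_length_estimate, d + 1L)
  expect_equal(prof$scc_score, 1.0)
})
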