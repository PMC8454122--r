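# k-means clustering of signal profiles, IgG cluster flagging, the
# configuration parser, and report assembly.

# build a signal_matrix object directly from an array of archetype profiles
mock_smat <- function(values, ids) {
  d <- dim(values)
  starts <- seq(0L, by = 2000L, length.out = d[2])
  structure(list(values = values, sample_ids = ids,
                 regions = data.frame(chrom = "chrM", start = starts,
                                      end = starts + 1000L),
                 bin_width = 1000L %/% d[3], normalization = "RPM"),
            class = "signal_matrix")
}

archetype_values <- function(n_per = 8L, bins = 10L, noise = 0.01, seed = 99L) {
  set.seed(seed)
  ids <- c("rep1", "rep2", "igg")
  profile <- list(shared = c(4, 4, 0), rep1_only = c(4, 0, 0),
                  igg_high = c(6, 6, 12))
  truth <- rep(names(profile), each = n_per)
  vals <- array(0, c(3, length(truth), bins))
  for (r in seq_along(truth))
    for (s in 1:3)
      vals[s, r, ] <- profile[[truth[r]]][s] +
        abs(rnorm(bins, 0, noise))
  list(values = vals, ids = ids, truth = truth)
}

test_that("clustering recovers archetype structure and relabels by signal", {
  av <- archetype_values()
  smat <- mock_smat(av$values, av$ids)
  cl <- cluster_regions(smat, k = 3, seed = 1)
  # exact recovery up to relabeling: one cluster per archetype
  expect_equal(length(unique(paste(av$truth, cl$assignments))), 3L)
  # cluster 1 carries the strongest mean signal (the igg_high block)
  expect_true(all(cl$assignments[av$truth == "igg_high"] == 1L))
  # deterministic under a fixed seed
  expect_identical(cl$assignments,
                   cluster_regions(smat, k = 3, seed = 1)$assignments)
  # rows are ordered by cluster id
  expect_true(!is.unsorted(cl$assignments[cl$row_order]))
})

test_that("k = 1 puts everything in one cluster; k > regions errors", {
  av <- archetype_values(n_per = 2L)
  smat <- mock_smat(av$values, av$ids)
  expect_equal(unique(cluster_regions(smat, k = 1)$assignments), 1L)
  expect_error(cluster_regions(smat, k = 7), "exceeds the number of regions")
  expect_error(cluster_regions(smat, k = 0), "k must be")
})

test_that("IgG-dominated clusters are flagged by the mean-ratio rule", {
  av <- archetype_values()
  smat <- mock_smat(av$values, av$ids)
  cl <- cluster_regions(smat, k = 3, seed = 1)
  flags <- igg_flag_clusters(cl, "igg")
  expect_equal(nrow(flags), 3L)
  # igg_high: mean igg 12 vs target 6 -> flagged; others have igg ~ 0
  expect_equal(flags$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(flags$mean_igg[1], 12, tolerance = 0.05)
  expect_equal(flags$mean_target[1], 6, tolerance = 0.05)

  # no IgG configured: warning, nothing flagged
  expect_warning(f0 <- igg_flag_clusters(cl, character(0)), "no IgG")
  expect_false(any(f0$flagged))

  # all-zero IgG signal: nothing flagged
  zv <- av$values
  zv[3, , ] <- 0
  cl0 <- cluster_regions(mock_smat(zv, av$ids), k = 3, seed = 1)
  expect_false(any(igg_flag_clusters(cl0, "igg")$flagged))

  expect_error(igg_flag_clusters(cl, c("rep1", "rep2", "igg")), "non-IgG")
  expect_error(igg_flag_clusters(cl, "nope"), "unknown IgG sample")
})

test_that("cluster ids are stable under sample column permutation", {
  av <- archetype_values()
  smat <- mock_smat(av$values, av$ids)
  perm <- c(3, 1, 2)
  smat_p <- mock_smat(av$values[perm, , , drop = FALSE], av$ids[perm])
  expect_equal(cluster_regions(smat, k = 3, seed = 1)$assignments,
               cluster_regions(smat_p, k = 3, seed = 1)$assignments)
})

test_that("config files parse with defaults, overrides and full validation", {
  d <- tempfile("cfg")
  dir.create(d)
  bam <- write_test_bam(data.frame(chrom = "chrT", start = 100L, width = 50L,
                                   strand = "+"), c(chrT = 10000L),
                        file.path(d, "s1.bam"))
  pk <- file.path(d, "s1.narrowPeak")
  writeLines("chrT\t100\t200\tp1\t0\t.\t5\t3\t2.5\t50", pk)

  cfg <- file.path(d, "run.csv")
  writeLines(c("sample_id,bam,peaks", "s1,s1.bam,s1.narrowPeak"), cfg)
  rc <- parse_config(cfg)
  expect_equal(rc$params$k, 6L)
  expect_equal(rc$params$bin_size, 10000L)
  expect_false(rc$samples$is_igg)

  writeLines(c("#k=4", "# bin_size=5000",
               "sample_id,bam,peaks,condition",
               "s1,s1.bam,s1.narrowPeak,frozen"), cfg)
  rc2 <- parse_config(cfg)
  expect_equal(rc2$params$k, 4L)
  expect_equal(rc2$params$bin_size, 5000L)
  expect_equal(rc2$samples$condition, "frozen")  # metadata preserved

  writeLines(c("sample_id,bam,peaks",
               "s1,s1.bam,s1.narrowPeak",
               "s1,s1.bam,missing.narrowPeak"), cfg)
  err <- tryCatch(parse_config(cfg), error = conditionMessage)
  expect_match(err, "duplicate sample_id: s1")
  expect_match(err, "missing.narrowPeak")
})

test_that("igg samples are recognised by id when no is_igg column exists", {
  d <- tempfile("cfg2")
  dir.create(d)
  bam <- write_test_bam(data.frame(chrom = "chrT", start = 100L, width = 50L,
                                   strand = "+"), c(chrT = 10000L),
                        file.path(d, "x.bam"))
  pk <- file.path(d, "x.narrowPeak")
  writeLines("chrT\t100\t200\tp1\t0\t.\t5\t3\t2.5\t50", pk)
  cfg <- file.path(d, "run.csv")
  writeLines(c("sample_id,bam,peaks",
               "IgG_ctrl,x.bam,x.narrowPeak",
               "h3k4me3,x.bam,x.narrowPeak"), cfg)
  expect_equal(parse_config(cfg)$samples$is_igg, c(TRUE, FALSE))
})

test_that("assemble_report records failures as NA with a reason", {
  metrics <- list(
    good = list(mapped_reads = list(value = 100L, reason = NA_character_),
                frip = list(value = 0.3, reason = NA_character_)),
    bad = list(mapped_reads = list(value = 0L, reason = NA_character_),
               frip = list(value = NA, reason = "no mapped reads")))
  rep <- assemble_report(metrics)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$frip[1], 0.3)
  expect_true(is.na(rep$frip[2]))
  expect_match(rep$na_reason[2], "no mapped reads")
  expect_equal(rep$na_reason[1], "")
})
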