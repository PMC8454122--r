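# Independent oracles and hand-built BAM fixtures. Oracles work per base
# on small coordinate ranges and never call the code paths they check.

# per-base boolean sweep: union of intervals as maximal runs of TRUE
sweep_merge <- function(df, max_coord = 10000L) {
  out <- list()
  for (chr in sort(unique(df$chrom))) {
    covered <- logical(max_coord)
    sub <- df[df$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      covered[seq.int(sub$start[i] + 1L, sub$end[i])] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep))
      out[[chr]] <- data.frame(chrom = chr, start = starts[keep] - 1L,
                               end = ends[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# brute-force membership: does any record of the set overlap the region?
sweep_membership <- function(regions, peak_sets) {
  m <- matrix(FALSE, nrow(regions), length(peak_sets))
  for (j in seq_along(peak_sets)) {
    rec <- peak_sets[[j]]$records
    for (i in seq_len(nrow(regions))) {
      m[i, j] <- any(rec$chrom == regions$chrom[i] &
                     rec$start < regions$end[i] &
                     rec$end > regions$start[i])
    }
  }
  m
}

# direct per-shift Pearson with the zero-variance -> 0 convention
brute_scc <- function(plus, minus, max_shift) {
  L <- length(plus)
  sapply(0:max_shift, function(k) {
    x <- plus[seq_len(L - k)]
    y <- minus[seq.int(k + 1L, L)]
    sx <- stats::sd(x)
    sy <- stats::sd(y)
    if (is.na(sx) || is.na(sy) || sx == 0 || sy == 0) 0
    else stats::cor(x, y)
  })
}

# drop the interval class tag and row names for comparison with plain oracles
plain <- function(df) {
  df <- df[, c("chrom", "start", "end"), drop = FALSE]
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}

random_intervals <- function(n, chroms = c("chrA", "chrB"),
                             max_coord = 10000L) {
  start <- sample.int(max_coord - 200L, n, replace = TRUE) - 1L
  width <- sample.int(150L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

make_peak_set <- function(df, sample_id, format = "narrowPeak") {
  n <- nrow(df)
  df$name <- as.character(seq_len(n))
  df$score <- rep(0L, n)
  df$strand <- rep(".", n)
  df$signal_value <- rep(1, n)
  df$p_value <- rep(3, n)
  df$q_value <- rep(2.5, n)
  df$summit_offset <- (df$end - df$start) %/% 2L
  cnrqc:::new_peak_set(sample_id, format, df)
}

# hand-built single-end BAM from an explicit alignment table:
# columns chrom, start (0-based), width, strand, mapq, dup (logical)
write_test_bam <- function(reads, chrom_sizes, bam_path,
                           unmapped = 0L, secondary = 0L) {
  n <- nrow(reads)
  if (n && is.null(reads$mapq)) reads$mapq <- 60L
  if (n && is.null(reads$dup)) reads$dup <- FALSE
  lines <- character(0)
  if (n) {
    flag <- ifelse(reads$strand == "-", 16L, 0L) + ifelse(reads$dup, 1024L, 0L)
    seqs <- vapply(reads$width, function(w) strrep("A", w), character(1))
    lines <- paste0("r", seq_len(n), "\t", flag, "\t", reads$chrom, "\t",
                    reads$start + 1L, "\t", reads$mapq, "\t",
                    reads$width, "M\t*\t0\t0\t", seqs, "\t*")
  }
  if (secondary > 0L && n > 0L) {
    lines <- c(lines, paste0("sec", seq_len(secondary), "\t256\t",
                             reads$chrom[1], "\t", reads$start[1] + 1L, "\t",
                             reads$mapq[1], "\t", reads$width[1],
                             "M\t*\t0\t0\t*\t*"))
  }
  if (unmapped > 0L)
    lines <- c(lines, paste0("u", seq_len(unmapped),
                             "\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"))
  cnrqc:::sam_to_bam(lines, chrom_sizes, bam_path)
  bam_path
}

tmp_path <- function(ext) tempfile(fileext = ext)
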