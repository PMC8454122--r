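## RPM-normalized signal matrices over fixed-width regions. Coverage comes
## from fragment pileup when the source is a BAM (paired: template span;
## single-end: reads extended to the estimated fragment length) or from a
## bigWig track used as-is.

bam_chrom_sizes <- function(bam_path) {
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  stats::setNames(as.integer(hdr), names(hdr))
}

## Fragment intervals (0-based half-open) for pileup from filtered reads.
fragment_intervals <- function(reads, fragment_length, chrom_sizes) {
  paired <- bitwAnd(reads$flag, 1L) > 0L
  out <- list()
  if (any(paired)) {
    # leftmost mate of each proper template carries isize > 0
    lm <- reads[paired & !is.na(reads$isize) & reads$isize > 0L, , drop = FALSE]
    if (nrow(lm))
      out$paired <- data.frame(chrom = lm$chrom, start = lm$start,
                               end = lm$start + lm$isize,
                               stringsAsFactors = FALSE)
  }
  se <- reads[!paired, , drop = FALSE]
  if (nrow(se)) {
    fl <- as.integer(fragment_length)
    start <- ifelse(se$strand == "-", se$end - fl, se$start)
    out$single <- data.frame(chrom = se$chrom,
                             start = pmax(0L, as.integer(start)),
                             end = as.integer(start) + fl,
                             stringsAsFactors = FALSE)
  }
  frag <- if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), start = integer(), end = integer())
  if (nrow(frag)) {
    len <- chrom_sizes[frag$chrom]
    frag$start <- pmax(frag$start, 0L)
    frag$end <- pmin(frag$end, as.integer(len))
    frag <- frag[frag$end > frag$start, , drop = FALSE]
  }
  frag
}

coverage_from_bam <- function(sample, fragment_length, chrom_sizes) {
  reads <- load_reads(sample$bam_path, sample$mapq_min, sample$dedup)
  frag <- fragment_intervals(reads, fragment_length, chrom_sizes)
  gr <- as_granges0(frag, seqlengths = chrom_sizes)
  GenomicRanges::coverage(gr)
}

coverage_from_bigwig <- function(bw_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("bigWig input requires the rtracklayer package")
  rtracklayer::import(rtracklayer::BigWigFile(bw_path), as = "RleList")
}

region_bin_means <- function(cov, regions, n_bins, bin_width) {
  out <- matrix(0, nrow(regions), n_bins)
  warned <- FALSE
  for (i in seq_len(nrow(regions))) {
    chr <- regions$chrom[i]
    if (!chr %in% names(cov)) {
      warned <- TRUE
      next
    }
    rc <- cov[[chr]]
    len <- length(rc)
    s1 <- regions$start[i] + 1L          # 1-based window
    e1 <- regions$end[i]
    if (s1 > len) {
      warned <- TRUE
      next
    }
    v <- as.numeric(S4Vectors::window(rc, s1, min(e1, len)))
    if (e1 > len) {                       # region runs off the chromosome
      v <- c(v, numeric(e1 - len))
      warned <- TRUE
    }
    out[i, ] <- colMeans(matrix(v, nrow = bin_width))
  }
  if (warned)
    warning("one or more regions extend past chromosome ends; ",
            "missing bases counted as zero coverage", call. = FALSE)
  out
}

#' Binned signal matrix over fixed-width regions
#'
#' For each sample, region and bin, the mean per-base coverage inside the
#' bin. BAM samples use fragment pileup (paired templates span mate to mate;
#' single-end reads are extended to \code{fragment_length} from their 5'
#' end) scaled to reads per million (RPM, factor 1e6 / mapped reads). bigWig
#' samples are used as-is and tagged \code{"raw"} unless declared
#' pre-normalized via \code{bigwig_normalized}.
#'
#' @param samples list of \code{sample_alignments}, or a named character
#'   vector of bigWig paths.
#' @param regions fixed-width intervals (all widths equal, divisible by
#'   \code{n_bins}).
#' @param n_bins number of bins per region (default 50).
#' @param fragment_length extension length for single-end BAM coverage
#'   (default 200 bp; ignored for paired templates and bigWig). A vector of
#'   one value per sample (e.g. per-sample SCC estimates) is accepted.
#' @param chrom_sizes named vector; defaults to the BAM header.
#' @param bigwig_normalized set TRUE if bigWig tracks are already RPM.
#' @return a \code{signal_matrix}: list with \code{values} (array samples x
#'   regions x bins), \code{sample_ids}, \code{regions}, \code{bin_width},
#'   \code{normalization}.
#' @export
signal_matrix <- function(samples, regions, n_bins = 50L,
                          fragment_length = 200L, chrom_sizes = NULL,
                          bigwig_normalized = FALSE) {
  validate_intervals(regions)
  widths <- unique(regions$end - regions$start)
  if (length(widths) != 1L)
    stop("all regions must have equal width")
  n_bins <- as.integer(n_bins)
  if (widths %% n_bins != 0L)
    stop("region width (", widths, ") must be divisible by n_bins (",
         n_bins, ")")
  bin_width <- widths %/% n_bins

  from_bigwig <- is.character(samples)
  if (from_bigwig) {
    ids <- names(samples)
    if (is.null(ids) || any(!nzchar(ids)))
      stop("bigWig paths must be named by sample id")
  } else {
    stopifnot(all(vapply(samples, inherits, logical(1), "sample_alignments")))
    ids <- vapply(samples, `[[`, character(1), "sample_id")
  }

  values <- array(0, dim = c(length(ids), nrow(regions), n_bins),
                  dimnames = list(ids, NULL, NULL))
  for (s in seq_along(ids)) {
    if (from_bigwig) {
      cov <- coverage_from_bigwig(samples[[s]])
      values[s, , ] <- region_bin_means(cov, regions, n_bins, bin_width)
    } else {
      smp <- samples[[s]]
      cs <- if (is.null(chrom_sizes)) bam_chrom_sizes(smp$bam_path)
            else chrom_sizes
      fl <- if (length(fragment_length) > 1L) fragment_length[[s]]
            else fragment_length
      cov <- coverage_from_bam(smp, fl, cs)
      scale <- if (smp$mapped_reads > 0L) 1e6 / smp$mapped_reads else 0
      values[s, , ] <- region_bin_means(cov, regions, n_bins, bin_width) * scale
    }
  }
  structure(list(values = values,
                 sample_ids = ids,
                 regions = regions,
                 bin_width = bin_width,
                 normalization = if (from_bigwig && !bigwig_normalized)
                   "raw" else "RPM"),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("signal_matrix: %d samples x %d regions x %d bins (%s, %d bp bins)\n",
              d[1], d[2], d[3], x$normalization, x$bin_width))
  invisible(x)
}

#' Export a signal matrix as a long-format TSV
#'
#' One row per (sample, region, bin) with region coordinates and RPM value.
#'
#' @param smat a \code{signal_matrix}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(smat, path) {
  stopifnot(inherits(smat, "signal_matrix"))
  d <- dim(smat$values)
  long <- data.frame(
    sample_id = rep(smat$sample_ids, each = d[2] * d[3]),
    chrom = rep(rep(smat$regions$chrom, each = d[3]), times = d[1]),
    start = rep(rep(smat$regions$start, each = d[3]), times = d[1]),
    end = rep(rep(smat$regions$end, each = d[3]), times = d[1]),
    bin = rep(rep(seq_len(d[3]), times = d[2]), times = d[1]),
    value = as.vector(aperm(smat$values, c(3, 2, 1))),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## region x (samples * bins) feature matrix used for clustering
signal_features <- function(smat) {
  d <- dim(smat$values)
  feat <- matrix(aperm(smat$values, c(2, 3, 1)), nrow = d[2])
  colnames(feat) <- paste(rep(smat$sample_ids, each = d[3]),
                          rep(seq_len(d[3]), times = d[1]), sep = ".")
  feat
}
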