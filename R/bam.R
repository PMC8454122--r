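## BAM-derived per-sample metrics: mapped-read counts, FRiP, and
## genome-wide binned counts with replicate correlations. All record access
## goes through Rsamtools; this file owns the single filtering policy
## (primary, mapped, MAPQ cutoff, optional duplicate removal) that every
## metric shares.

bam_flag_filter <- function(dedup) {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE,
                         isDuplicate = if (dedup) FALSE else NA)
}

ensure_bam_index <- function(bam_path) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  idx <- paste0(bam_path, ".bai")
  if (!file.exists(idx)) {
    message("indexing ", bam_path)
    tryCatch(Rsamtools::indexBam(bam_path),
             error = function(e) stop("BAM has no index and indexing failed: ",
                                      conditionMessage(e)))
  }
  invisible(bam_path)
}

## Load filtered primary alignments as a data frame in 0-based half-open
## coordinates: chrom, start (leftmost aligned base), end, strand, isize,
## flag. Shared by frip/binned_counts/signal/SCC so counting rules agree.
load_reads <- function(bam_path, mapq_min = 20L, dedup = TRUE) {
  ensure_bam_index(bam_path)
  param <- Rsamtools::ScanBamParam(
    flag = bam_flag_filter(dedup),
    mapqFilter = as.integer(mapq_min),
    what = c("rname", "pos", "qwidth", "strand", "isize", "flag"))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  n <- length(res$pos)
  keep <- if (n) !is.na(res$pos) else logical(0)
  data.frame(chrom = as.character(res$rname)[keep],
             start = res$pos[keep] - 1L,
             end = res$pos[keep] - 1L + res$qwidth[keep],
             strand = as.character(res$strand)[keep],
             isize = res$isize[keep],
             flag = res$flag[keep],
             stringsAsFactors = FALSE)
}

#' Scan a BAM file for per-sample alignment statistics
#'
#' Counts primary mapped alignments passing the MAPQ cutoff, excluding
#' secondary and supplementary records and (optionally) duplicate-flagged
#' reads. For paired data both mates count toward \code{mapped_reads}.
#'
#' @param bam_path coordinate-sorted BAM; indexed, or indexable in place.
#' @param mapq_min minimum mapping quality (default 20).
#' @param dedup drop duplicate-flagged reads (default TRUE).
#' @param sample_id label; defaults to file name without extension.
#' @return a \code{sample_alignments}: list with \code{sample_id},
#'   \code{bam_path}, \code{mapped_reads}, \code{read_length} (modal query
#'   length, NA when no reads), \code{paired}, and the filter settings used.
#' @export
scan_bam <- function(bam_path, mapq_min = 20L, dedup = TRUE,
                     sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(bam_path))
  reads <- load_reads(bam_path, mapq_min, dedup)
  read_length <- if (nrow(reads)) {
    w <- table(reads$end - reads$start)
    as.integer(names(w)[which.max(w)])
  } else NA_integer_
  structure(list(sample_id = sample_id,
                 bam_path = bam_path,
                 mapped_reads = nrow(reads),
                 read_length = read_length,
                 paired = nrow(reads) > 0 && any(bitwAnd(reads$flag, 1L) > 0L),
                 mapq_min = as.integer(mapq_min),
                 dedup = dedup),
            class = "sample_alignments")
}

#' @export
print.sample_alignments <- function(x, ...) {
  cat(sprintf("sample_alignments '%s': %d mapped reads, read length %s, %s\n",
              x$sample_id, x$mapped_reads,
              ifelse(is.na(x$read_length), "NA", x$read_length),
              if (x$paired) "paired" else "single-end"))
  invisible(x)
}

#' Fraction of reads in peaks (FRiP)
#'
#' Reads overlapping any peak by at least 1 bp over the aligned span,
#' divided by all mapped reads under the same filters as
#' \code{\link{scan_bam}}. The counting unit is reads (paired mates count
#' individually in numerator and denominator).
#'
#' @param sample a \code{sample_alignments} from \code{\link{scan_bam}}.
#' @param peaks a \code{peak_set} or interval data frame.
#' @return FRiP in [0, 1].
#' @export
frip <- function(sample, peaks) {
  stopifnot(inherits(sample, "sample_alignments"))
  if (sample$mapped_reads == 0L)
    stop("FRiP undefined: sample '", sample$sample_id,
         "' has no mapped reads")
  rec <- if (inherits(peaks, "peak_set")) peaks$records else peaks
  if (nrow(rec) == 0L) return(0)
  reads <- load_reads(sample$bam_path, sample$mapq_min, sample$dedup)
  hits <- GenomicRanges::countOverlaps(
    as_granges0(reads[, c("chrom", "start", "end")]),
    as_granges0(rec[, c("chrom", "start", "end")]),
    ignore.strand = TRUE)
  sum(hits > 0L) / sample$mapped_reads
}

#' Genome-wide binned read counts
#'
#' Each filtered read is assigned to exactly one bin by its 5' position
#' (leftmost aligned base on the plus strand, rightmost on the minus
#' strand); half-open bins, so a 5' end exactly at a boundary falls in the
#' following bin.
#'
#' @param sample a \code{sample_alignments}.
#' @param chrom_sizes named integer vector.
#' @param bin_size bin width in bp (default 10000).
#' @return a \code{binned_counts}: list with \code{sample_id}, \code{bins}
#'   (from \code{\link{tile_genome}}) and integer \code{counts}.
#' @export
binned_counts <- function(sample, chrom_sizes, bin_size = 10000L) {
  stopifnot(inherits(sample, "sample_alignments"))
  bins <- tile_genome(chrom_sizes, bin_size)
  counts <- integer(nrow(bins))
  reads <- load_reads(sample$bam_path, sample$mapq_min, sample$dedup)
  if (nrow(reads)) {
    five <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
    for (chr in names(chrom_sizes)) {
      sel <- reads$chrom == chr & five >= 0L & five < chrom_sizes[[chr]]
      if (!any(sel)) next
      idx_chr <- which(bins$chrom == chr)
      bi <- five[sel] %/% as.integer(bin_size) + 1L
      tab <- tabulate(bi, nbins = length(idx_chr))
      counts[idx_chr] <- counts[idx_chr] + tab
    }
  }
  structure(list(sample_id = sample$sample_id, bins = bins,
                 counts = counts),
            class = "binned_counts")
}

#' Correlation of binned counts between two samples
#'
#' Pearson correlation of (optionally log1p-transformed) bin counts; bins
#' where both samples are zero are retained.
#'
#' @param a,b \code{binned_counts} over identical bins.
#' @param transform \code{"log1p"} (default) or \code{"raw"}.
#' @return Pearson correlation in [-1, 1].
#' @export
count_correlation <- function(a, b, transform = c("log1p", "raw")) {
  transform <- match.arg(transform)
  stopifnot(inherits(a, "binned_counts"), inherits(b, "binned_counts"))
  if (!identical(a$bins[, c("chrom", "start", "end")],
                 b$bins[, c("chrom", "start", "end")]))
    stop("binned counts computed over different bins")
  x <- a$counts
  y <- b$counts
  if (transform == "log1p") {
    x <- log1p(x)
    y <- log1p(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("count correlation undefined: zero variance in '",
         if (stats::sd(x) == 0) a$sample_id else b$sample_id, "'")
  stats::cor(x, y)
}
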