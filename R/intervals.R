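## Interval algebra on 0-based half-open coordinates (BED convention).
## Every public function in the package speaks this coordinate system;
## conversion to the 1-based closed system used by IRanges/GenomicRanges
## happens only inside the two helpers below.

#' Construct a genomic interval table
#'
#' Intervals are plain data frames with columns \code{chrom}, \code{start},
#' \code{end} and optionally \code{strand}, in 0-based half-open (BED)
#' coordinates: a base at position p is covered by \code{[start, end)} iff
#' \code{start <= p < end}.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector in \code{c("+", "-", ".")}.
#' @return data frame with class \code{c("genomic_intervals", "data.frame")}.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end", call. = FALSE)
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
    stop("chrom must be non-empty", call. = FALSE)
  invisible(df)
}

## 0-based half-open -> GRanges (1-based closed)
as_granges0 <- function(df, seqlengths = NULL) {
  strand <- if ("strand" %in% names(df)) as.character(df$strand)
            else rep("*", nrow(df))
  strand <- rep_len(strand, nrow(df))
  strand[is.na(strand) | strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

## GRanges -> 0-based half-open data frame
as_intervals0 <- function(gr) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Merge overlapping and touching intervals
#'
#' Returns the minimal sorted set of disjoint intervals covering exactly the
#' union of the inputs. Intervals that touch end-to-start (\code{end ==
#' start}) on the same chromosome are merged, so the output never contains
#' zero-gap splits. Strand is ignored.
#'
#' @param intervals data frame with \code{chrom}, \code{start}, \code{end}.
#' @return sorted \code{genomic_intervals} data frame of disjoint intervals.
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  gr <- as_granges0(intervals)
  GenomicRanges::strand(gr) <- "*"
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  out <- as_intervals0(GenomicRanges::sort(red, ignore.strand = TRUE))
  sort_intervals(out)
}

#' Resize intervals to a fixed width
#'
#' Each interval is replaced by a window of exactly \code{width} bp anchored
#' on its center (default) or on its summit. Windows whose left edge would
#' fall below 0 are shifted right so the full width is preserved.
#'
#' @param intervals data frame with \code{chrom}, \code{start}, \code{end};
#'   for \code{anchor = "summit"} also \code{summit_offset} (offset from
#'   \code{start}, >= 0).
#' @param width target width in bp (> 0).
#' @param anchor \code{"center"} or \code{"summit"}.
#' @return \code{genomic_intervals} of constant width, same row order.
#' @export
resize_fixed_width <- function(intervals, width, anchor = c("center", "summit")) {
  anchor <- match.arg(anchor)
  validate_intervals(intervals)
  width <- as.integer(width)
  if (width <= 0L) stop("width must be > 0")
  if (nrow(intervals) == 0L)
    return(genomic_intervals(character(), integer(), integer()))
  if (anchor == "summit") {
    if (!"summit_offset" %in% names(intervals) ||
        any(intervals$summit_offset < 0L))
      stop("anchor = 'summit' requires summit_offset >= 0 for every interval")
    point <- intervals$start + intervals$summit_offset
  } else {
    point <- (intervals$start + intervals$end) %/% 2L
  }
  start <- point - width %/% 2L
  shift <- pmax(0L, -start)   # clip at 0 preserves width by shifting right
  start <- start + shift
  out <- data.frame(chrom = intervals$chrom,
                    start = as.integer(start),
                    end = as.integer(start + width),
                    strand = if ("strand" %in% names(intervals))
                      intervals$strand else ".",
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Tile a genome into fixed-size bins
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin_size bin width in bp (> 0); the final bin on each chromosome is
#'   truncated at the chromosome end.
#' @return \code{genomic_intervals} in chromosome order as given, then
#'   position.
#' @export
tile_genome <- function(chrom_sizes, bin_size) {
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0L) stop("bin_size must be > 0")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  pieces <- lapply(names(chrom_sizes), function(chr) {
    len <- as.integer(chrom_sizes[[chr]])
    starts <- seq.int(0L, len - 1L, by = bin_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + bin_size, len),
               strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path two-column whitespace-separated text file: chromosome name,
#'   length.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  stats::setNames(as.integer(df$length), df$chrom)
}

#' Write a chrom.sizes file
#' @param chrom_sizes named integer vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(paste(names(chrom_sizes), as.integer(chrom_sizes), sep = "\t"),
             path)
  invisible(path)
}
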