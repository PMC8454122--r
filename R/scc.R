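## Strand cross-correlation (SCC). Read 5' ends are tallied per strand over
## each region; the two profiles are correlated at progressive shifts of the
## minus strand toward the plus strand. The shift that superimposes the two
## 5'-end profiles corresponds to the library fragment length: a fragment of
## length F puts its plus 5' end at s and its minus 5' end at s + F - 1, so
## shift k maps to fragment length k + 1 throughout this module. A secondary
## ("phantom") maximum at the read length marks mapping artifacts; regions
## whose correlation at read length exceeds a threshold are flagged.

#' Per-strand 5'-end position vectors over a region
#'
#' Plus-strand reads contribute at their leftmost aligned base, minus-strand
#' reads at their rightmost aligned base.
#'
#' @param sample a \code{sample_alignments}, or a read table from an earlier
#'   scan (internal use).
#' @param region one-row interval data frame or list with \code{chrom},
#'   \code{start}, \code{end}.
#' @return list with integer vectors \code{plus} and \code{minus}, each of
#'   length \code{end - start}.
#' @export
strand_position_vectors <- function(sample, region) {
  reads <- if (inherits(sample, "sample_alignments"))
    load_reads(sample$bam_path, sample$mapq_min, sample$dedup)
  else sample
  L <- region$end - region$start
  if (L <= 0L) stop("region width must be > 0")
  sel <- reads$chrom == region$chrom
  five <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
  off <- five - region$start + 1L                  # 1-based offset in region
  inside <- sel & off >= 1L & off <= L
  plus <- tabulate(off[inside & reads$strand != "-"], nbins = L)
  minus <- tabulate(off[inside & reads$strand == "-"], nbins = L)
  list(plus = plus, minus = minus)
}

#' Strand cross-correlation curve
#'
#' For each shift k in 0..max_shift, the Pearson correlation between
#' \code{plus[1..L-k]} and \code{minus[(k+1)..L]} (the minus profile slid
#' toward the plus profile). Shifts where either slice has zero variance
#' yield correlation 0.
#'
#' @param plus,minus equal-length numeric count vectors.
#' @param max_shift largest shift in bp; must be < vector length.
#' @return numeric vector of length \code{max_shift + 1} (shifts 0..max).
#' @export
scc_curve <- function(plus, minus, max_shift) {
  L <- length(plus)
  if (length(minus) != L) stop("plus and minus vectors differ in length")
  max_shift <- as.integer(max_shift)
  if (max_shift < 0L || max_shift >= L)
    stop("max_shift must satisfy 0 <= max_shift < vector length (", L, ")")
  plus <- as.numeric(plus)
  minus <- as.numeric(minus)
  cx <- cumsum(plus)
  cxx <- cumsum(plus * plus)
  ry <- rev(cumsum(rev(minus)))                # ry[i] = sum(minus[i..L])
  ryy <- rev(cumsum(rev(minus * minus)))
  out <- numeric(max_shift + 1L)
  for (k in 0:max_shift) {
    n <- L - k
    sx <- cx[n]
    sy <- ry[k + 1L]
    vx <- cxx[n] - sx * sx / n
    vy <- ryy[k + 1L] - sy * sy / n
    if (vx <= 0 || vy <= 0) next               # zero variance -> 0
    sxy <- sum(plus[seq_len(n)] * minus[seq.int(k + 1L, L)])
    out[k + 1L] <- (sxy - sx * sy / n) / sqrt(vx * vy)
  }
  pmin(pmax(out, -1), 1)
}

## curve value at a given fragment length (shift = length - 1)
corr_at_length <- function(correlations, len) {
  if (is.na(len) || len < 1L || len > length(correlations)) return(NA_real_)
  correlations[[len]]
}

#' Per-region strand cross-correlation
#'
#' @param sample a \code{sample_alignments}.
#' @param regions interval data frame (typically fixed-width consensus
#'   regions).
#' @param max_shift largest shift; default \code{min(min width - 1, 500)}.
#' @return a \code{region_scc}: list with \code{regions}, \code{shifts}
#'   (0..max_shift), \code{correlations} (matrix regions x shifts),
#'   \code{read_counts} (reads per region), \code{read_length},
#'   \code{sample_id}.
#' @export
region_scc <- function(sample, regions, max_shift = NULL) {
  stopifnot(inherits(sample, "sample_alignments"))
  validate_intervals(regions)
  widths <- regions$end - regions$start
  if (is.null(max_shift)) max_shift <- min(min(widths) - 1L, 500L)
  max_shift <- as.integer(max_shift)
  if (any(max_shift >= widths))
    stop("max_shift (", max_shift, ") must be smaller than every region width")
  reads <- load_reads(sample$bam_path, sample$mapq_min, sample$dedup)
  n <- nrow(regions)
  cors <- matrix(0, n, max_shift + 1L)
  counts <- integer(n)
  ## pre-split read 5' ends by chromosome once
  five <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
  neg <- reads$strand == "-"
  by_chr <- split(data.frame(five = five, neg = neg), reads$chrom)
  for (i in seq_len(n)) {
    ch <- by_chr[[regions$chrom[i]]]
    L <- widths[i]
    if (is.null(ch)) next
    off <- ch$five - regions$start[i] + 1L
    inside <- off >= 1L & off <= L
    counts[i] <- sum(inside)
    if (!counts[i]) next
    plus <- tabulate(off[inside & !ch$neg], nbins = L)
    minus <- tabulate(off[inside & ch$neg], nbins = L)
    cors[i, ] <- scc_curve(plus, minus, max_shift)
  }
  structure(list(regions = regions, shifts = 0:max_shift,
                 correlations = cors, read_counts = counts,
                 read_length = sample$read_length,
                 sample_id = sample$sample_id),
            class = "region_scc")
}

#' Average strand cross-correlation profile
#'
#' Element-wise weighted mean of per-region curves; regions without reads
#' are excluded. The fragment length is then estimated from the averaged
#' curve with the read-length window excluded.
#'
#' @param per_region a \code{region_scc}.
#' @param weights \code{"uniform"} or \code{"by_read_count"}.
#' @param exclusion_halfwidth half-width (bp) of the read-length exclusion
#'   window used for the fragment-length estimate (default 10).
#' @return an \code{scc_profile}: list with \code{shifts},
#'   \code{correlations}, \code{fragment_length_estimate},
#'   \code{read_length}, \code{n_regions}, \code{scc_score} (correlation of
#'   the averaged curve at the estimated fragment length).
#' @export
average_scc <- function(per_region, weights = c("uniform", "by_read_count"),
                        exclusion_halfwidth = 10L) {
  weights <- match.arg(weights)
  stopifnot(inherits(per_region, "region_scc"))
  keep <- per_region$read_counts > 0L
  if (!any(keep))
    stop("SCC average undefined: no region contains reads")
  w <- if (weights == "uniform") rep(1, sum(keep))
       else per_region$read_counts[keep]
  w <- w / sum(w)
  avg <- as.numeric(w %*% per_region$correlations[keep, , drop = FALSE])
  fl <- estimate_fragment_length(avg, per_region$read_length,
                                 exclusion_halfwidth)
  structure(list(shifts = per_region$shifts,
                 correlations = avg,
                 fragment_length_estimate = fl,
                 read_length = per_region$read_length,
                 n_regions = sum(keep),
                 scc_score = corr_at_length(avg, fl),
                 sample_id = per_region$sample_id),
            class = "scc_profile")
}

#' @export
print.scc_profile <- function(x, ...) {
  cat(sprintf("scc_profile '%s': %d regions, fragment length %d bp, read length %s bp, SCC score %.3f\n",
              x$sample_id, x$n_regions, x$fragment_length_estimate,
              ifelse(is.na(x$read_length), "NA", x$read_length), x$scc_score))
  invisible(x)
}

#' Estimate fragment length from an SCC curve
#'
#' Argmax of the correlation curve in fragment-length units (shift + 1),
#' excluding the phantom window \code{read_length +/- exclusion_halfwidth};
#' ties are broken toward the larger shift.
#'
#' @param profile an \code{scc_profile} or a numeric correlation vector over
#'   shifts 0..max_shift.
#' @param read_length read length in bp (taken from the profile when
#'   omitted).
#' @param exclusion_halfwidth half-width of the exclusion window in bp.
#' @return estimated fragment length in bp.
#' @export
estimate_fragment_length <- function(profile, read_length = NULL,
                                     exclusion_halfwidth = 10L) {
  if (inherits(profile, "scc_profile")) {
    if (is.null(read_length)) read_length <- profile$read_length
    correlations <- profile$correlations
  } else correlations <- as.numeric(profile)
  if (exclusion_halfwidth < 0L) stop("exclusion_halfwidth must be >= 0")
  lengths <- seq_along(correlations)           # shift k -> length k + 1
  keep <- if (is.null(read_length) || is.na(read_length)) {
    rep(TRUE, length(lengths))
  } else abs(lengths - read_length) > exclusion_halfwidth
  if (!any(keep))
    stop("exclusion window covers every shift; reduce exclusion_halfwidth ",
         "or increase max_shift")
  cand <- which(keep)
  best <- max(cand[correlations[cand] == max(correlations[cand])])
  lengths[best]
}

#' Flag artifact regions by read-length correlation
#'
#' Regions whose strand cross-correlation at the read length exceeds
#' \code{threshold} are dominated by the phantom (mapping-artifact) peak and
#' flagged as likely artifacts. Also reports the correlation at the
#' estimated fragment length, backing the fragment-vs-read-length scatter.
#'
#' @param per_region a \code{region_scc}.
#' @param fragment_length estimated fragment length in bp (e.g. from
#'   \code{\link{average_scc}}).
#' @param read_length read length in bp; defaults to the scan's modal value.
#' @param threshold flag when correlation at read length exceeds this value
#'   (default 0.9); in (0, 1].
#' @return data frame: region coordinates, \code{n_reads},
#'   \code{corr_at_read_length}, \code{corr_at_fragment_length},
#'   \code{artifact_flag}.
#' @export
flag_artifact_regions <- function(per_region, fragment_length,
                                  read_length = NULL, threshold = 0.9) {
  stopifnot(inherits(per_region, "region_scc"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (is.null(read_length)) read_length <- per_region$read_length
  crl <- apply(per_region$correlations, 1L, corr_at_length, read_length)
  cfl <- apply(per_region$correlations, 1L, corr_at_length, fragment_length)
  out <- cbind(per_region$regions[, c("chrom", "start", "end")],
               data.frame(n_reads = per_region$read_counts,
                          corr_at_read_length = crl,
                          corr_at_fragment_length = cfl,
                          artifact_flag = !is.na(crl) & crl > threshold))
  rownames(out) <- NULL
  out
}
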