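## Consensus peak sets and overlap summaries: merged union regions, a
## boolean membership matrix (region x sample), upset-style combination
## counts, pairwise Jaccard, and the binary-heatmap row ordering.

#' Build a consensus peak set across samples
#'
#' Consensus regions are the merged union of all peak records; a sample is a
#' member of a region when at least one of its peaks overlaps the region by
#' at least \code{min_overlap} bp.
#'
#' @param peak_sets list of \code{peak_set} objects with distinct sample ids.
#' @param min_overlap minimum overlap in bp defining membership (default 1).
#' @return a \code{consensus_set}: list with \code{regions} (sorted disjoint
#'   intervals), \code{membership} (logical matrix, regions x samples),
#'   \code{sample_ids} and \code{n_peaks} (original per-sample record
#'   counts).
#' @export
build_consensus <- function(peak_sets, min_overlap = 1L) {
  if (length(peak_sets) == 0L)
    stop("build_consensus requires at least one peak set")
  stopifnot(all(vapply(peak_sets, inherits, logical(1), "peak_set")))
  ids <- vapply(peak_sets, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])

  all_rec <- do.call(rbind, lapply(peak_sets, function(p)
    p$records[, c("chrom", "start", "end")]))
  regions <- merge_intervals(all_rec)
  region_gr <- as_granges0(regions)

  membership <- matrix(FALSE, nrow = nrow(regions), ncol = length(ids),
                       dimnames = list(NULL, ids))
  for (j in seq_along(peak_sets)) {
    rec <- peak_sets[[j]]$records
    if (nrow(rec) == 0L) next
    hits <- GenomicRanges::countOverlaps(
      region_gr, as_granges0(rec),
      minoverlap = as.integer(min_overlap), ignore.strand = TRUE)
    membership[, j] <- hits > 0L
  }
  structure(list(regions = regions,
                 membership = membership,
                 sample_ids = ids,
                 n_peaks = stats::setNames(
                   vapply(peak_sets, function(p) nrow(p$records), integer(1)),
                   ids)),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d regions x %d samples (%s)\n",
              nrow(x$regions), length(x$sample_ids),
              paste(x$sample_ids, collapse = ", ")))
  invisible(x)
}

membership_pattern <- function(membership, sample_ids) {
  apply(membership, 1L, function(row)
    paste(sample_ids[row], collapse = "&"))
}

#' Summarize consensus overlaps
#'
#' @param consensus a \code{consensus_set}.
#' @return list with \code{set_counts} (original peak count per sample),
#'   \code{combination_counts} (named integer vector keyed by membership
#'   pattern, e.g. \code{"A&B"}; sums to the number of consensus regions) and
#'   \code{pairwise_jaccard} (matrix; \code{J[i,j]} = regions with both /
#'   regions with either).
#' @export
summarize_overlaps <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_set"))
  m <- consensus$membership
  ids <- consensus$sample_ids
  patterns <- membership_pattern(m, ids)
  combo <- table(patterns)
  combination_counts <- stats::setNames(as.integer(combo), names(combo))

  n <- length(ids)
  jac <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    un <- sum(m[, i] | m[, j])
    jac[i, j] <- if (un == 0L) NA_real_ else sum(m[, i] & m[, j]) / un
  }
  list(set_counts = consensus$n_peaks,
       combination_counts = combination_counts,
       pairwise_jaccard = jac)
}

#' Region table ordered for a binary membership heatmap
#'
#' Rows are grouped by membership pattern; patterns are ordered by
#' descending region count, ties broken by pattern string; within a pattern
#' the original (coordinate) region order is preserved.
#'
#' @param consensus a \code{consensus_set}.
#' @return data frame: region coordinates, one logical column per sample and
#'   a \code{pattern} column, in heatmap row order.
#' @export
binary_heatmap_table <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_set"))
  m <- consensus$membership
  out <- cbind(consensus$regions[, c("chrom", "start", "end")],
               as.data.frame(m))
  if (nrow(out) == 0L) {
    out$pattern <- character()
    return(out)
  }
  out$pattern <- membership_pattern(m, consensus$sample_ids)
  counts <- table(out$pattern)
  ord <- order(-as.integer(counts[out$pattern]), out$pattern,
               seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write consensus regions as BED6
#'
#' The name column carries the membership pattern (e.g. \code{"A&B"}).
#'
#' @param consensus a \code{consensus_set}.
#' @param path output path.
#' @param keep optional logical vector selecting regions to write.
#' @return `path`, invisibly.
#' @export
write_consensus_bed <- function(consensus, path, keep = NULL) {
  stopifnot(inherits(consensus, "consensus_set"))
  reg <- consensus$regions
  pat <- if (nrow(reg)) membership_pattern(consensus$membership,
                                           consensus$sample_ids) else character()
  if (!is.null(keep)) {
    reg <- reg[keep, , drop = FALSE]
    pat <- pat[keep]
  }
  lines <- if (nrow(reg))
    paste(reg$chrom, reg$start, reg$end, pat, 0L, ".", sep = "\t")
  else character()
  writeLines(lines, path)
  invisible(path)
}

#' Venn counts for up to three peak sets
#'
#' @param consensus a \code{consensus_set} with at most 3 samples.
#' @return named integer vector of region counts per membership combination.
#' @export
venn_counts <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_set"))
  if (length(consensus$sample_ids) > 3L)
    stop("venn counts support at most 3 sets; use summarize_overlaps ",
         "combination counts for more")
  summarize_overlaps(consensus)$combination_counts
}
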