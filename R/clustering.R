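## k-means clustering of region signal profiles and IgG-control artifact
## flagging. Cluster ids are relabeled so cluster 1 always carries the
## strongest mean signal, making ids stable across runs and across sample
## column permutations of the matrix.

#' Cluster consensus regions by their signal profiles
#'
#' k-means (Lloyd, Euclidean) on one feature vector per region formed by
#' concatenating every sample's bins. Clusters are relabeled by descending
#' mean signal; rows are ordered by cluster, then by descending region mean,
#' giving a deterministic heatmap layout.
#'
#' @param smat a \code{signal_matrix}.
#' @param k number of clusters (default 6); must be <= number of regions.
#' @param seed RNG seed for the restarts (default 0).
#' @param nstart random restarts, lowest within-cluster SS kept (default 10).
#' @param scale_rows divide each region's features by its max (default
#'   FALSE: cluster raw RPM values).
#' @return a \code{clustered_matrix}: list with \code{matrix} (the input),
#'   \code{assignments} (cluster id per region, 1..k), \code{cluster_order},
#'   \code{row_order}, \code{k}, \code{seed}.
#' @export
cluster_regions <- function(smat, k = 6L, seed = 0L, nstart = 10L,
                            scale_rows = FALSE) {
  stopifnot(inherits(smat, "signal_matrix"))
  k <- as.integer(k)
  n_regions <- nrow(smat$regions)
  if (k < 1L) stop("k must be >= 1")
  if (k > n_regions)
    stop("k (", k, ") exceeds the number of regions (", n_regions, ")")
  feat <- signal_features(smat)
  if (scale_rows) {
    mx <- apply(feat, 1L, max)
    feat <- feat / ifelse(mx > 0, mx, 1)
  }
  if (k == 1L) {
    assign <- rep(1L, n_regions)
  } else {
    set.seed(as.integer(seed))
    km <- tryCatch(
      stats::kmeans(feat, centers = k, nstart = nstart, iter.max = 200L,
                    algorithm = "Lloyd"),
      error = function(e) {
        # Lloyd can abandon a start on an empty cluster; retry with H-W
        set.seed(as.integer(seed))
        stats::kmeans(feat, centers = k, nstart = nstart, iter.max = 200L)
      })
    assign <- as.integer(km$cluster)
  }
  ## relabel by descending mean signal across all samples
  cl_mean <- tapply(rowMeans(feat), assign, mean)
  relabel <- stats::setNames(rank(-cl_mean, ties.method = "first"),
                             names(cl_mean))
  assignments <- as.integer(relabel[as.character(assign)])
  row_order <- order(assignments, -rowMeans(feat))
  structure(list(matrix = smat,
                 assignments = assignments,
                 cluster_order = seq_len(k),
                 row_order = row_order,
                 k = k,
                 seed = as.integer(seed)),
            class = "clustered_matrix")
}

#' @export
print.clustered_matrix <- function(x, ...) {
  cat(sprintf("clustered_matrix: %d regions in %d clusters (sizes: %s)\n",
              length(x$assignments), x$k,
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' Flag clusters dominated by IgG-control signal
#'
#' Regions where a non-specific IgG control shows signal comparable to the
#' targeted samples are background/artifact rather than specific binding.
#' Per cluster, the mean RPM over IgG samples is compared with the mean over
#' target samples; clusters with \code{mean_igg >= flag_ratio * mean_target}
#' (and non-zero IgG signal) are flagged.
#'
#' @param clustered a \code{clustered_matrix}.
#' @param igg_sample_ids sample ids of IgG controls (subset of the matrix's
#'   samples; at least one non-IgG sample must remain).
#' @param flag_ratio IgG/target mean ratio at which a cluster is flagged
#'   (default 1.0).
#' @return data frame: \code{cluster}, \code{n_regions}, \code{mean_igg},
#'   \code{mean_target}, \code{flagged}.
#' @export
igg_flag_clusters <- function(clustered, igg_sample_ids, flag_ratio = 1.0) {
  stopifnot(inherits(clustered, "clustered_matrix"))
  smat <- clustered$matrix
  ids <- smat$sample_ids
  if (!all(igg_sample_ids %in% ids))
    stop("unknown IgG sample id(s): ",
         paste(setdiff(igg_sample_ids, ids), collapse = ", "))
  target_ids <- setdiff(ids, igg_sample_ids)
  if (length(target_ids) == 0L)
    stop("at least one non-IgG sample is required")
  k <- clustered$k
  out <- data.frame(cluster = seq_len(k),
                    n_regions = tabulate(clustered$assignments, k),
                    mean_igg = NA_real_, mean_target = NA_real_,
                    flagged = FALSE)
  region_mean <- function(sel_idx, regions_sel) {
    if (!length(sel_idx) || !sum(regions_sel)) return(0)
    mean(smat$values[sel_idx, regions_sel, , drop = FALSE])
  }
  igg_idx <- which(ids %in% igg_sample_ids)
  target_idx <- which(ids %in% target_ids)
  for (cl in seq_len(k)) {
    sel <- clustered$assignments == cl
    out$mean_igg[cl] <- region_mean(igg_idx, sel)
    out$mean_target[cl] <- region_mean(target_idx, sel)
  }
  if (length(igg_sample_ids) == 0L) {
    warning("no IgG samples configured; nothing flagged", call. = FALSE)
    return(out)
  }
  out$flagged <- out$mean_igg > 0 &
    out$mean_igg >= flag_ratio * out$mean_target
  out
}
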