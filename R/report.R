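## The end-to-end QC pipeline: scan BAMs, parse and filter peaks, build the
## consensus set and overlap summaries, binned replicate correlations,
## per-sample SCC with fragment-length estimation and artifact flags, the
## RPM signal matrix with k-means clustering and IgG cluster flagging, and
## the per-sample CSV report plus plot-ready tables. Per-sample metric
## failures are recorded as NA with a reason, never raised.

try_metric <- function(expr) {
  tryCatch(list(value = expr, reason = NA_character_),
           error = function(e) list(value = NA, reason = conditionMessage(e)))
}

#' Assemble the per-sample QC report table
#'
#' @param metrics named list (by sample id) of per-sample metric lists; each
#'   metric is a list with \code{value} and \code{reason} (NA when the
#'   metric succeeded).
#' @param correlations optional square matrix of pairwise binned-count
#'   correlations (adds one \code{cor_<sample>} column per sample).
#' @return data frame, one row per sample, with stable column order and an
#'   \code{na_reason} column collecting failure reasons.
#' @export
assemble_report <- function(metrics, correlations = NULL) {
  fields <- c("mapped_reads", "read_length", "paired", "peak_count",
              "peak_count_after_qfilter", "frip",
              "fragment_length_estimate", "scc_score", "n_artifact_regions")
  rows <- lapply(names(metrics), function(sid) {
    m <- metrics[[sid]]
    vals <- lapply(fields, function(f)
      if (is.null(m[[f]])) NA else m[[f]]$value)
    names(vals) <- fields
    reasons <- unlist(lapply(fields, function(f) {
      r <- m[[f]]$reason
      if (is.null(r) || is.na(r)) NULL else paste0(f, ": ", r)
    }))
    row <- data.frame(sample_id = sid, stringsAsFactors = FALSE)
    for (f in fields) row[[f]] <- if (is.null(vals[[f]])) NA else vals[[f]]
    if (!is.null(correlations)) {
      for (other in colnames(correlations))
        row[[paste0("cor_", other)]] <- correlations[sid, other]
    }
    row$na_reason <- if (length(reasons)) paste(reasons, collapse = "; ")
                     else ""
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full QC pipeline
#'
#' Executes every stage on the configured samples and writes
#' \code{qc_report.csv}, \code{consensus.bed}, \code{consensus_filtered.bed}
#' (flagged IgG-dominated clusters removed), \code{overlap_counts.csv},
#' \code{binary_heatmap.csv}, \code{correlation_matrix.csv},
#' \code{scc_per_region.csv}, \code{scc_average.csv},
#' \code{signal_matrix.tsv}, \code{clusters.csv} and
#' \code{cluster_summary.csv} to the output directory. The run is
#' deterministic given (inputs, parameters, seed); with a cache directory
#' configured, reruns reuse cached per-sample results and produce identical
#' files.
#'
#' @param config a \code{run_config} from \code{\link{parse_config}}, or a
#'   path to a configuration file.
#' @param out_dir output directory (default: the config's
#'   \code{output_dir}).
#' @param cache use the configured \code{cache_dir} (default TRUE; FALSE
#'   forces recomputation).
#' @param quiet suppress progress messages.
#' @return a \code{qc_run}: list with \code{report} (data frame),
#'   \code{consensus}, \code{overlaps}, \code{correlations}, \code{scc}
#'   (per-sample profiles), \code{signal}, \code{clustered},
#'   \code{cluster_flags}, \code{files} (paths written).
#' @export
run_qc <- function(config, out_dir = NULL, cache = TRUE, quiet = FALSE) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  if (is.null(out_dir)) out_dir <- p$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- if (cache && !is.na(p$cache_dir)) p$cache_dir else NULL
  say <- function(...) if (!quiet) message(...)
  samples <- config$samples
  ids <- samples$sample_id
  n <- length(ids)

  ## -- per-sample scans and peaks ------------------------------------------
  scans <- list()
  peaks <- list()
  metrics <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    sid <- ids[i]
    say("scanning ", sid, " (", basename(samples$bam[i]), ")")
    scans[[sid]] <- with_cache(
      cache_dir,
      list("scan_bam", file_sig(samples$bam[i]), p$mapq_min, p$dedup),
      function() scan_bam(samples$bam[i], p$mapq_min, p$dedup,
                          sample_id = sid))
    peaks[[sid]] <- read_peaks(samples$peaks[i], samples$peak_format[i],
                               sample_id = sid)
    metrics[[sid]]$mapped_reads <- list(value = scans[[sid]]$mapped_reads,
                                        reason = NA_character_)
    metrics[[sid]]$read_length <- list(value = scans[[sid]]$read_length,
                                       reason = NA_character_)
    metrics[[sid]]$paired <- list(value = scans[[sid]]$paired,
                                  reason = NA_character_)
    metrics[[sid]]$peak_count <- list(value = nrow(peaks[[sid]]$records),
                                      reason = NA_character_)
    metrics[[sid]]$peak_count_after_qfilter <- try_metric(
      nrow(suppressWarnings(filter_by_qvalue(peaks[[sid]], p$min_q))$records))
    metrics[[sid]]$frip <- try_metric(frip(scans[[sid]], peaks[[sid]]))
  }

  ## -- consensus & overlaps ------------------------------------------------
  say("building consensus over ", n, " peak sets")
  consensus <- build_consensus(unname(peaks))
  overlaps <- summarize_overlaps(consensus)
  files <- c(consensus = file.path(out_dir, "consensus.bed"))
  write_consensus_bed(consensus, files[["consensus"]])
  files[["overlap_counts"]] <- file.path(out_dir, "overlap_counts.csv")
  write_csv_stable(data.frame(combination = names(overlaps$combination_counts),
                              n_regions = unname(overlaps$combination_counts)),
                   files[["overlap_counts"]])
  files[["binary_heatmap"]] <- file.path(out_dir, "binary_heatmap.csv")
  write_csv_stable(binary_heatmap_table(consensus), files[["binary_heatmap"]])

  ## -- binned correlations -------------------------------------------------
  chrom_sizes <- bam_chrom_sizes(samples$bam[1])
  say("binned counts (", p$bin_size, " bp) and correlations")
  bc <- lapply(ids, function(sid) with_cache(
    cache_dir,
    list("binned_counts", file_sig(scans[[sid]]$bam_path), p$mapq_min,
         p$dedup, p$bin_size),
    function() binned_counts(scans[[sid]], chrom_sizes, p$bin_size)))
  names(bc) <- ids
  correlations <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    correlations[i, j] <- tryCatch(
      count_correlation(bc[[i]], bc[[j]], p$cor_transform),
      error = function(e) NA_real_)
  }
  files[["correlation_matrix"]] <- file.path(out_dir, "correlation_matrix.csv")
  write_csv_stable(cbind(data.frame(sample_id = ids),
                         as.data.frame(correlations)),
                   files[["correlation_matrix"]])

  ## -- fixed-width windows, SCC --------------------------------------------
  windows <- resize_fixed_width(consensus$regions, p$window_width, "center")
  max_shift <- min(p$max_shift, p$window_width - 1L)
  scc_profiles <- list()
  scc_tables <- list()
  frag_lengths <- stats::setNames(rep(200L, n), ids)
  for (sid in ids) {
    say("SCC: ", sid)
    res <- try_metric({
      rs <- with_cache(
        cache_dir,
        list("region_scc", file_sig(scans[[sid]]$bam_path), p$mapq_min,
             p$dedup, windows, max_shift),
        function() region_scc(scans[[sid]], windows, max_shift))
      prof <- average_scc(rs, exclusion_halfwidth = p$exclusion_halfwidth)
      flags <- flag_artifact_regions(rs, prof$fragment_length_estimate,
                                     threshold = p$artifact_threshold)
      list(profile = prof, flags = flags)
    })
    if (is.na(res$reason)) {
      prof <- res$value$profile
      scc_profiles[[sid]] <- prof
      scc_tables[[sid]] <- cbind(sample_id = sid, res$value$flags)
      frag_lengths[sid] <- prof$fragment_length_estimate
      metrics[[sid]]$fragment_length_estimate <-
        list(value = prof$fragment_length_estimate, reason = NA_character_)
      metrics[[sid]]$scc_score <- list(value = prof$scc_score,
                                       reason = NA_character_)
      metrics[[sid]]$n_artifact_regions <-
        list(value = sum(res$value$flags$artifact_flag),
             reason = NA_character_)
    } else {
      for (f in c("fragment_length_estimate", "scc_score",
                  "n_artifact_regions"))
        metrics[[sid]][[f]] <- list(value = NA, reason = res$reason)
    }
  }
  files[["scc_per_region"]] <- file.path(out_dir, "scc_per_region.csv")
  write_csv_stable(do.call(rbind, c(scc_tables, list(make.row.names = FALSE))),
                   files[["scc_per_region"]])
  files[["scc_average"]] <- file.path(out_dir, "scc_average.csv")
  avg_tab <- do.call(rbind, lapply(scc_profiles, function(pr)
    data.frame(sample_id = pr$sample_id, shift = pr$shifts,
               correlation = pr$correlations)))
  write_csv_stable(avg_tab, files[["scc_average"]])

  ## -- signal matrix, clustering, IgG flags --------------------------------
  say("signal matrix over ", nrow(windows), " windows")
  smat <- with_cache(
    cache_dir,
    list("signal_matrix", lapply(samples$bam, file_sig), p$mapq_min, p$dedup,
         windows, p$n_bins, unname(frag_lengths)),
    function() signal_matrix(unname(scans), windows, n_bins = p$n_bins,
                             fragment_length = unname(frag_lengths),
                             chrom_sizes = chrom_sizes))
  files[["signal_matrix"]] <- file.path(out_dir, "signal_matrix.tsv")
  write_signal_matrix(smat, files[["signal_matrix"]])
  k_eff <- min(p$k, nrow(windows))
  if (k_eff < p$k)
    warning("k reduced to the number of regions (", k_eff, ")", call. = FALSE)
  say("k-means clustering, k = ", k_eff)
  clustered <- cluster_regions(smat, k = k_eff, seed = p$seed)
  igg_ids <- ids[samples$is_igg]
  cluster_flags <- if (length(igg_ids) && length(igg_ids) < n)
    igg_flag_clusters(clustered, igg_ids, p$flag_ratio)
  else {
    if (!length(igg_ids))
      warning("no IgG samples configured; no clusters flagged", call. = FALSE)
    data.frame(cluster = seq_len(k_eff),
               n_regions = tabulate(clustered$assignments, k_eff),
               mean_igg = NA_real_, mean_target = NA_real_, flagged = FALSE)
  }
  files[["clusters"]] <- file.path(out_dir, "clusters.csv")
  flagged_cl <- cluster_flags$cluster[cluster_flags$flagged]
  cl_tab <- cbind(consensus$regions[, c("chrom", "start", "end")],
                  data.frame(cluster = clustered$assignments,
                             flagged = clustered$assignments %in% flagged_cl))
  write_csv_stable(cl_tab[clustered$row_order, ], files[["clusters"]])
  files[["cluster_summary"]] <- file.path(out_dir, "cluster_summary.csv")
  write_csv_stable(cluster_flags, files[["cluster_summary"]])
  files[["consensus_filtered"]] <- file.path(out_dir, "consensus_filtered.bed")
  write_consensus_bed(consensus, files[["consensus_filtered"]],
                      keep = !(clustered$assignments %in% flagged_cl))

  ## -- report ---------------------------------------------------------------
  report <- assemble_report(metrics, correlations)
  files[["qc_report"]] <- file.path(out_dir, "qc_report.csv")
  write_csv_stable(report, files[["qc_report"]])
  say("wrote ", files[["qc_report"]])
  structure(list(report = report, consensus = consensus, overlaps = overlaps,
                 correlations = correlations, scc = scc_profiles,
                 signal = smat, clustered = clustered,
                 cluster_flags = cluster_flags, files = files,
                 params = p),
            class = "qc_run")
}

#' @export
print.qc_run <- function(x, ...) {
  cat("qc_run:", nrow(x$report), "samples,",
      nrow(x$consensus$regions), "consensus regions,",
      sum(x$cluster_flags$flagged), "flagged cluster(s)\n")
  print(x$report[, c("sample_id", "mapped_reads", "peak_count", "frip",
                     "fragment_length_estimate", "scc_score")])
  invisible(x)
}
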