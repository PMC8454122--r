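## Thin base-graphics layer over the exported tables. The correctness
## surface of the package is the tables; these helpers exist for quick
## visual inspection.

#' Plot an averaged strand cross-correlation profile
#'
#' Correlation against fragment length (shift + 1), with the estimated
#' fragment length in blue and the read length in red.
#'
#' @param profile an \code{scc_profile}.
#' @param ... passed to \code{plot}.
#' @return the profile, invisibly.
#' @export
plot_scc <- function(profile, ...) {
  stopifnot(inherits(profile, "scc_profile"))
  graphics::plot(profile$shifts + 1L, profile$correlations, type = "l",
                 xlab = "fragment length (bp)", ylab = "cross-correlation",
                 main = profile$sample_id, ...)
  graphics::abline(v = profile$fragment_length_estimate, col = "blue",
                   lty = 2)
  if (!is.na(profile$read_length))
    graphics::abline(v = profile$read_length, col = "red", lty = 2)
  invisible(profile)
}

#' Plot the binary membership heatmap of a consensus set
#'
#' @param consensus a \code{consensus_set}.
#' @return the heatmap table, invisibly.
#' @export
plot_binary_heatmap <- function(consensus) {
  tab <- binary_heatmap_table(consensus)
  ids <- consensus$sample_ids
  m <- as.matrix(tab[, ids, drop = FALSE]) * 1
  graphics::image(x = seq_along(ids), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = c("grey90", "grey20"), axes = FALSE,
                  xlab = "", ylab = "consensus regions")
  graphics::axis(1, at = seq_along(ids), labels = ids, las = 2)
  invisible(tab)
}
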