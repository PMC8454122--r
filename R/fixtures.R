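## Synthetic, ground-truth-annotated test data: a mini-genome, peak files in
## all three dialects, and pre-aligned reads written as SAM and converted to
## a coordinate-sorted indexed BAM. Fragments are placed inside true peaks
## with probability frip_target (peak choice weighted by per-peak enrichment,
## position uniform within the peak) and uniformly on the background
## otherwise; each fragment emits a plus-strand read at its left end and, if
## paired, a minus-strand mate at its right end. Truth (realized FRiP,
## per-peak counts, fragment lengths) is recorded with the same counting
## rules the metrics use.

#' Specification for a synthetic sample
#'
#' @param chrom_sizes named integer vector (default one 1 Mb contig).
#' @param true_peaks interval data frame with optional \code{enrichment}
#'   multiplier column; default ten 400 bp peaks evenly spaced.
#' @param fragment_length_mean,fragment_length_sd fragment-length
#'   distribution in bp (truncated normal, minimum \code{2 * read_length};
#'   defaults 180 / 30, typical of a nucleosomal CUT&RUN library).
#' @param read_length read length in bp (default 50).
#' @param n_fragments number of fragments to simulate (default 10000).
#' @param frip_target probability a fragment is placed inside a peak
#'   (default 0.3).
#' @param paired emit paired-end reads (default TRUE).
#' @param duplicate_rate per-fragment probability of emitting one
#'   duplicate-flagged copy (default 0).
#' @param seed RNG seed.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(chrom_sizes = c(chrSim = 1000000L),
                         true_peaks = NULL,
                         fragment_length_mean = 180,
                         fragment_length_sd = 30,
                         read_length = 50L,
                         n_fragments = 10000L,
                         frip_target = 0.3,
                         paired = TRUE,
                         duplicate_rate = 0,
                         seed = 0L) {
  if (is.null(true_peaks)) {
    len <- chrom_sizes[[1]]
    starts <- as.integer(round(seq(len * 0.05, len * 0.9, length.out = 10)))
    true_peaks <- data.frame(chrom = names(chrom_sizes)[1],
                             start = starts, end = starts + 400L,
                             enrichment = 1, stringsAsFactors = FALSE)
  }
  if (!"enrichment" %in% names(true_peaks)) true_peaks$enrichment <- 1
  validate_intervals(true_peaks)
  spec <- structure(list(chrom_sizes = chrom_sizes, true_peaks = true_peaks,
                         fragment_length_mean = fragment_length_mean,
                         fragment_length_sd = fragment_length_sd,
                         read_length = as.integer(read_length),
                         n_fragments = as.integer(n_fragments),
                         frip_target = frip_target,
                         paired = paired,
                         duplicate_rate = duplicate_rate,
                         seed = as.integer(seed)),
                    class = "fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  if (spec$fragment_length_mean <= spec$read_length)
    stop("fragment_length_mean must exceed read_length")
  if (spec$frip_target < 0 || spec$frip_target > 1 ||
      spec$duplicate_rate < 0 || spec$duplicate_rate > 1)
    stop("frip_target and duplicate_rate must be in [0, 1]")
  tp <- spec$true_peaks
  if (!all(tp$chrom %in% names(spec$chrom_sizes)))
    stop("true peaks reference unknown chromosomes")
  if (any(tp$end > spec$chrom_sizes[tp$chrom]))
    stop("true peaks extend past chromosome ends")
  invisible(spec)
}

## write SAM records and convert to a sorted, indexed BAM
sam_to_bam <- function(sam_lines, chrom_sizes, bam_path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(chrom_sizes),
                  "\tLN:", as.integer(chrom_sizes)))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeLines(c(hdr, sam_lines), sam)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
  bam_path
}

#' Simulate aligned reads for one sample
#'
#' @param spec a \code{fixture_spec}.
#' @param bam_path output BAM path (index written alongside).
#' @param sample_id sample label (default from the BAM file name).
#' @return list with \code{bam} (path), \code{sample_id}, \code{spec} and
#'   \code{truth}: \code{realized_frip} (fraction of emitted primary reads
#'   whose aligned span overlaps a true peak, duplicates included),
#'   \code{n_reads}, \code{n_fragments}, \code{per_peak_counts} (fragments
#'   assigned to each true peak), \code{fragment_lengths} (realized),
#'   \code{true_fragment_length} (the spec mean).
#' @export
simulate_sample <- function(spec, bam_path, sample_id = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  validate_fixture_spec(spec)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(bam_path))
  set.seed(spec$seed)
  n <- spec$n_fragments
  rl <- spec$read_length
  tp <- spec$true_peaks

  flen <- if (spec$fragment_length_sd == 0) {
    rep(as.integer(round(spec$fragment_length_mean)), n)
  } else {
    pmax(2L * rl, as.integer(round(stats::rnorm(
      n, spec$fragment_length_mean, spec$fragment_length_sd))))
  }

  in_peak <- stats::runif(n) < spec$frip_target
  peak_idx <- rep(NA_integer_, n)
  chrom <- character(n)
  start <- integer(n)
  if (any(in_peak)) {
    pk <- sample.int(nrow(tp), sum(in_peak), replace = TRUE,
                     prob = tp$enrichment)
    peak_idx[in_peak] <- pk
    pw <- tp$end[pk] - tp$start[pk]
    fl <- flen[in_peak]
    room <- pw - fl
    s <- ifelse(room >= 0L,
                tp$start[pk] + floor(stats::runif(length(pk)) * (room + 1)),
                tp$start[pk] + room %/% 2L)     # fragment longer than peak: center it
    len <- spec$chrom_sizes[tp$chrom[pk]]
    s <- pmin(pmax(as.integer(s), 0L), as.integer(len) - fl)
    chrom[in_peak] <- tp$chrom[pk]
    start[in_peak] <- s
  }
  if (any(!in_peak)) {
    cs <- spec$chrom_sizes
    ci <- sample.int(length(cs), sum(!in_peak), replace = TRUE,
                     prob = as.numeric(cs))
    fl <- flen[!in_peak]
    len <- as.integer(cs[ci])
    s <- floor(stats::runif(sum(!in_peak)) * pmax(1L, len - fl + 1L))
    chrom[!in_peak] <- names(cs)[ci]
    start[!in_peak] <- as.integer(s)
  }

  dup <- stats::runif(n) < spec$duplicate_rate
  idx <- c(seq_len(n), which(dup))              # duplicate copies appended
  is_dup <- c(rep(FALSE, n), rep(TRUE, sum(dup)))
  f_chrom <- chrom[idx]
  f_start <- start[idx]
  f_len <- flen[idx]
  f_end <- f_start + f_len
  qname <- paste0("frag_", idx, ifelse(is_dup, "_dup", ""))
  seq1 <- strrep("A", rl)
  cig <- paste0(rl, "M")

  if (spec$paired) {
    dupflag <- ifelse(is_dup, 1024L, 0L)
    r1 <- paste(qname, 99L + dupflag, f_chrom, f_start + 1L, 60L, cig, "=",
                f_end - rl + 1L, f_len, seq1, "*", sep = "\t")
    r2 <- paste(qname, 147L + dupflag, f_chrom, f_end - rl + 1L, 60L, cig,
                "=", f_start + 1L, -f_len, seq1, "*", sep = "\t")
    sam_lines <- c(rbind(r1, r2))
    read_chrom <- rep(f_chrom, each = 2L)
    read_start <- as.integer(rbind(f_start, f_end - rl))
  } else {
    minus <- stats::runif(length(idx)) < 0.5    # sequence either fragment end
    flag <- ifelse(minus, 16L, 0L) + ifelse(is_dup, 1024L, 0L)
    pos <- ifelse(minus, f_end - rl, f_start)
    sam_lines <- paste(qname, flag, f_chrom, pos + 1L, 60L, cig, "*", 0L, 0L,
                       seq1, "*", sep = "\t")
    read_chrom <- f_chrom
    read_start <- as.integer(pos)
  }
  sam_to_bam(sam_lines, spec$chrom_sizes, bam_path)

  ## realized FRiP: per emitted read, aligned span vs true peaks (>= 1 bp)
  reads <- data.frame(chrom = read_chrom, start = read_start,
                      end = read_start + rl, stringsAsFactors = FALSE)
  hits <- GenomicRanges::countOverlaps(
    as_granges0(reads), as_granges0(tp[, c("chrom", "start", "end")]),
    ignore.strand = TRUE)
  truth <- list(realized_frip = sum(hits > 0L) / nrow(reads),
                n_reads = nrow(reads),
                n_fragments = length(idx),
                per_peak_counts = tabulate(peak_idx[idx], nrow(tp)),
                fragment_lengths = as.integer(f_len),
                true_fragment_length = spec$fragment_length_mean,
                read_length = rl,
                frip_target = spec$frip_target,
                seed = spec$seed)
  list(bam = bam_path, sample_id = sample_id, spec = spec, truth = truth)
}

#' Write true peaks in a chosen peak-file dialect
#'
#' Synthetic q-values are drawn so that a configurable fraction of peaks
#' fails a given -log10 q threshold, for filter testing.
#'
#' @param spec a \code{fixture_spec} (its \code{true_peaks} are written).
#' @param path output path.
#' @param dialect \code{"narrowPeak"}, \code{"broadPeak"} or \code{"seacr"}.
#' @param q_fail_fraction fraction of peaks given q-values below
#'   \code{q_threshold} (default 0).
#' @param q_threshold -log10 q-value boundary (default 2).
#' @param seed RNG seed for the q-value draw.
#' @return `path`, invisibly.
#' @export
simulate_peak_files <- function(spec, path,
                                dialect = c("narrowPeak", "broadPeak", "seacr"),
                                q_fail_fraction = 0, q_threshold = 2,
                                seed = spec$seed + 1L) {
  dialect <- match.arg(dialect)
  tp <- spec$true_peaks
  n <- nrow(tp)
  set.seed(as.integer(seed))
  fail <- stats::runif(n) < q_fail_fraction
  q <- ifelse(fail, stats::runif(n, 0, q_threshold),
              stats::runif(n, q_threshold, q_threshold + 10))
  width <- tp$end - tp$start
  lines <- switch(dialect,
    narrowPeak = paste(tp$chrom, tp$start, tp$end,
                       paste0("peak_", seq_len(n)),
                       pmin(1000L, as.integer(round(100 * tp$enrichment))),
                       ".", format(tp$enrichment, trim = TRUE),
                       format(q + 1, trim = TRUE, digits = 6),
                       format(q, trim = TRUE, digits = 6),
                       width %/% 2L, sep = "\t"),
    broadPeak = paste(tp$chrom, tp$start, tp$end,
                      paste0("peak_", seq_len(n)),
                      pmin(1000L, as.integer(round(100 * tp$enrichment))),
                      ".", format(tp$enrichment, trim = TRUE),
                      format(q + 1, trim = TRUE, digits = 6),
                      format(q, trim = TRUE, digits = 6), sep = "\t"),
    seacr = paste(tp$chrom, tp$start, tp$end,
                  format(tp$enrichment * width, trim = TRUE),
                  format(tp$enrichment, trim = TRUE),
                  paste0(tp$chrom, ":", tp$start, "-", tp$end), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Multi-sample fixture bundle with cluster archetypes
#'
#' Emits two target "replicates" and one IgG control whose expected signal
#' matrix has block structure over three kinds of regions: \code{shared}
#' (enriched in both replicates), \code{sample1_only} (first replicate
#' only), and \code{igg_high} (enriched in all samples, strongest in IgG —
#' the background/artifact archetype). Writes per-sample BAMs and narrowPeak
#' files, a chrom.sizes file, a ready-to-run config, and a truth table
#' (JSON) mapping each region to its archetype.
#'
#' @param out_dir output directory (created if needed).
#' @param n_regions_per_archetype regions per archetype (default 12).
#' @param archetypes subset of \code{c("shared", "sample1_only",
#'   "igg_high")}, at least two.
#' @param n_fragments fragments per sample (default 30000).
#' @param read_length,fragment_length_mean,fragment_length_sd see
#'   \code{\link{fixture_spec}}.
#' @param region_width width of true peak regions in bp (default 400).
#' @param seed RNG seed; per-sample seeds are derived from it.
#' @return list with \code{config} (path), \code{samples} (data frame:
#'   sample_id, bam, peaks, is_igg), \code{truth} (region archetype table),
#'   \code{chrom_sizes}, \code{sims} (per-sample \code{simulate_sample}
#'   results).
#' @export
make_cluster_archetypes <- function(out_dir,
                                    n_regions_per_archetype = 12L,
                                    archetypes = c("shared", "sample1_only",
                                                   "igg_high"),
                                    n_fragments = 30000L,
                                    read_length = 50L,
                                    fragment_length_mean = 180,
                                    fragment_length_sd = 30,
                                    region_width = 400L,
                                    seed = 0L) {
  archetypes <- match.arg(archetypes, several.ok = TRUE)
  if (length(archetypes) < 2L) stop("need at least two archetypes")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_arch <- length(archetypes)
  n_reg <- n_arch * n_regions_per_archetype
  spacing <- 3000L
  chrom_len <- as.integer(n_reg * spacing + 20000L)
  chrom_sizes <- c(chrFix = chrom_len)
  starts <- as.integer(10000L + (seq_len(n_reg) - 1L) * spacing)
  set.seed(as.integer(seed))
  arch <- sample(rep(archetypes, each = n_regions_per_archetype))
  regions <- data.frame(chrom = "chrFix", start = starts,
                        end = starts + as.integer(region_width),
                        archetype = arch, stringsAsFactors = FALSE)

  ## per-sample enrichment multipliers over the archetypes
  mult <- list(
    rep1 = c(shared = 1, sample1_only = 1, igg_high = 1),
    rep2 = c(shared = 1, sample1_only = 0, igg_high = 1),
    igg  = c(shared = 0, sample1_only = 0, igg_high = 1))
  frip <- c(rep1 = 0.7, rep2 = 0.7, igg = 0.5)

  sims <- list()
  rows <- list()
  for (i in seq_along(mult)) {
    sid <- names(mult)[i]
    m <- mult[[i]][regions$archetype]
    peaks <- regions[m > 0, c("chrom", "start", "end"), drop = FALSE]
    peaks$enrichment <- m[m > 0]
    spec <- fixture_spec(chrom_sizes = chrom_sizes, true_peaks = peaks,
                         fragment_length_mean = fragment_length_mean,
                         fragment_length_sd = fragment_length_sd,
                         read_length = read_length,
                         n_fragments = n_fragments,
                         frip_target = unname(frip[sid]),
                         paired = TRUE,
                         seed = as.integer(seed) + i)
    bam <- file.path(out_dir, paste0(sid, ".bam"))
    pk <- file.path(out_dir, paste0(sid, ".narrowPeak"))
    sims[[sid]] <- simulate_sample(spec, bam, sample_id = sid)
    simulate_peak_files(spec, pk, "narrowPeak")
    rows[[sid]] <- data.frame(sample_id = sid, bam = basename(bam),
                              peaks = basename(pk),
                              peak_format = "narrowPeak",
                              is_igg = sid == "igg",
                              stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  write_chrom_sizes(chrom_sizes, file.path(out_dir, "chrom.sizes"))
  jsonlite::write_json(regions, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  config <- file.path(out_dir, "config.csv")
  write_config(samples, config, params = list(seed = as.integer(seed)))
  list(config = config, samples = samples, truth = regions,
       chrom_sizes = chrom_sizes, sims = sims)
}
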