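## Peak file I/O: ENCODE narrowPeak (BED6+4), broadPeak (BED6+3) and the
## 6-column SEACR bed dialect. A parsed peak set is a list with the sample
## id, the format tag, and a records data frame holding one row per peak in
## a uniform schema regardless of dialect.

PEAK_COLUMNS <- c("chrom", "start", "end", "name", "score", "strand",
                  "signal_value", "p_value", "q_value", "summit_offset")

new_peak_set <- function(sample_id, format, records) {
  records <- records[order(records$chrom, records$start, records$end), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(list(sample_id = sample_id, format = format, records = records),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s' (%s): %d records\n",
              x$sample_id, x$format, nrow(x$records)))
  invisible(x)
}

empty_peak_records <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = integer(), strand = character(),
             signal_value = numeric(), p_value = numeric(),
             q_value = numeric(), summit_offset = integer(),
             stringsAsFactors = FALSE)
}

#' Read a peak file
#'
#' Parses ENCODE narrowPeak (10 columns), broadPeak (9 columns, no summit) or
#' SEACR bed (6 columns) into a uniform record table. Lines starting with
#' \code{#} or \code{track} are skipped. SEACR files carry no p/q-values:
#' total signal is stored in \code{signal_value}, the max-signal region
#' string in \code{name}, and \code{p_value}/\code{q_value} are set to -1
#' (the narrowPeak missing-value convention).
#'
#' @param path path to a tab-separated peak file.
#' @param format one of \code{"narrowPeak"}, \code{"broadPeak"},
#'   \code{"seacr"}.
#' @param sample_id sample label; defaults to the file name without
#'   extension.
#' @return a \code{peak_set}: list with \code{sample_id}, \code{format} and
#'   \code{records} sorted by (chrom, start, end).
#' @export
read_peaks <- function(path, format = c("narrowPeak", "broadPeak", "seacr"),
                       sample_id = NULL) {
  if (length(format) == 1L && !format %in% c("narrowPeak", "broadPeak", "seacr"))
    stop("unknown peak format: '", format,
         "' (expected narrowPeak, broadPeak or seacr)")
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track)", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(new_peak_set(sample_id, format, empty_peak_records()))

  ncol_expect <- switch(format, narrowPeak = 10L, broadPeak = 9L, seacr = 6L)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < ncol_expect))
    stop(sprintf("malformed %s line %d in %s: expected %d columns, got %d",
                 format, line_no[which(nf < ncol_expect)[1]], path,
                 ncol_expect, nf[which(nf < ncol_expect)[1]]))
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_expect)))

  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad))
    stop(sprintf("malformed coordinates at line %d in %s: start='%s' end='%s'",
                 line_no[bad[1]], path, m[bad[1], 2], m[bad[1], 3]))

  records <- switch(format,
    narrowPeak = data.frame(
      chrom = m[, 1], start = start, end = end, name = m[, 4],
      score = as.integer(m[, 5]), strand = m[, 6],
      signal_value = as.numeric(m[, 7]), p_value = as.numeric(m[, 8]),
      q_value = as.numeric(m[, 9]), summit_offset = as.integer(m[, 10]),
      stringsAsFactors = FALSE),
    broadPeak = data.frame(
      chrom = m[, 1], start = start, end = end, name = m[, 4],
      score = as.integer(m[, 5]), strand = m[, 6],
      signal_value = as.numeric(m[, 7]), p_value = as.numeric(m[, 8]),
      q_value = as.numeric(m[, 9]), summit_offset = -1L,
      stringsAsFactors = FALSE),
    seacr = data.frame(
      chrom = m[, 1], start = start, end = end, name = m[, 6],
      score = 0L, strand = ".",
      signal_value = as.numeric(m[, 4]), p_value = -1, q_value = -1,
      summit_offset = -1L, stringsAsFactors = FALSE))

  bad_summit <- with(records, summit_offset != -1L &
                     (summit_offset < 0L | summit_offset >= end - start))
  if (any(bad_summit))
    stop(sprintf("summit offset out of range at line %d in %s",
                 line_no[which(bad_summit)[1]], path))
  new_peak_set(sample_id, format, records)
}

#' Write peaks as narrowPeak or BED6
#'
#' @param peaks a \code{peak_set} or a peak-record data frame.
#' @param path output path.
#' @param format \code{"narrowPeak"} (all 10 columns) or \code{"bed6"}.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  rec <- if (inherits(peaks, "peak_set")) peaks$records else peaks
  num <- function(x) {
    # canonical numeric rendering: integers without decimal point
    vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE,
                                 digits = 15), character(1))
  }
  lines <- if (format == "narrowPeak") {
    paste(rec$chrom, rec$start, rec$end, rec$name, rec$score, rec$strand,
          num(rec$signal_value), num(rec$p_value), num(rec$q_value),
          rec$summit_offset, sep = "\t")
  } else {
    name <- if ("name" %in% names(rec)) rec$name else "."
    score <- if ("score" %in% names(rec)) rec$score else 0L
    strand <- if ("strand" %in% names(rec)) rec$strand else "."
    paste(rec$chrom, rec$start, rec$end, name, score, strand, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Filter peaks by q-value
#'
#' Keeps records at least as significant as \code{min_q} on the -log10
#' scale (\code{q_value >= min_q}). Records with \code{q_value == -1}
#' (missing, e.g. every SEACR peak) are retained unchanged with a warning,
#' since dropping all peaks of a caller that emits no q-values would be
#' wrong.
#'
#' @param peaks a \code{peak_set}.
#' @param min_q minimum -log10 q-value, >= 0.
#' @return a new \code{peak_set}; the input is not modified.
#' @export
filter_by_qvalue <- function(peaks, min_q) {
  stopifnot(inherits(peaks, "peak_set"))
  if (min_q < 0) stop("min_q must be >= 0")
  rec <- peaks$records
  missing_q <- rec$q_value == -1
  if (any(missing_q))
    warning(sum(missing_q), " record(s) without q-values (q_value == -1) ",
            "retained unfiltered", call. = FALSE)
  keep <- missing_q | rec$q_value >= min_q
  new_peak_set(peaks$sample_id, peaks$format,
               rec[keep, , drop = FALSE])
}
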