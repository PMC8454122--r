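## Plain-text run configuration: a comma- or tab-separated sample table with
## a header, preceded by optional "#key=value" lines overriding global
## parameters. Unknown sample columns are kept as metadata.

default_params <- function() {
  list(bin_size = 10000L,        # bp, genome-wide correlation bins
       k = 6L,                   # k-means clusters
       window_width = 2000L,     # bp, fixed width of consensus windows
       n_bins = 50L,             # bins per window
       mapq_min = 20L,
       dedup = TRUE,
       min_q = 2,                # -log10 q-value peak filter for reporting
       max_shift = 500L,         # bp, SCC
       exclusion_halfwidth = 10L,# bp, SCC phantom-peak exclusion
       artifact_threshold = 0.9, # SCC corr at read length
       flag_ratio = 1.0,         # IgG/target mean RPM ratio
       cor_transform = "log1p",
       seed = 0L,
       cache_dir = NA_character_,
       output_dir = ".")
}

coerce_param <- function(key, value, template) {
  ref <- template[[key]]
  if (is.logical(ref)) as.logical(value)
  else if (is.integer(ref)) as.integer(value)
  else if (is.numeric(ref)) as.numeric(value)
  else as.character(value)
}

#' Parse a run configuration file
#'
#' The file holds one row per sample with required columns \code{sample_id},
#' \code{bam}, \code{peaks}; optional columns \code{peak_format} (default
#' narrowPeak), \code{bigwig}, \code{is_igg}, and any grouping metadata
#' (kept verbatim). Header lines of the form \code{#key=value} override
#' global parameters (e.g. \code{#k=4}); every absent parameter gets its
#' default. Samples whose \code{sample_id} contains "igg"
#' (case-insensitive) are treated as IgG controls when no \code{is_igg}
#' column is present. All validation problems are reported at once.
#'
#' @param path configuration file path.
#' @return a \code{run_config}: list with \code{samples} (data frame) and
#'   \code{params} (named list).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_param <- grepl("^#", lines)
  params <- default_params()
  for (ln in sub("^#\\s*", "", lines[is_param])) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(params)) {
      warning("unknown config parameter '", key, "' ignored", call. = FALSE)
      next
    }
    params[[key]] <- coerce_param(key, val, params)
  }
  body <- lines[!is_param & nzchar(trimws(lines))]
  if (length(body) < 2L)
    stop("config must contain a header line and at least one sample row")
  sep <- if (grepl("\t", body[1], fixed = TRUE)) "\t" else ","
  samples <- utils::read.table(text = body, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)

  problems <- character()
  for (col in c("sample_id", "bam", "peaks"))
    if (!col %in% names(samples))
      problems <- c(problems, paste0("missing required column '", col, "'"))
  if ("sample_id" %in% names(samples)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    if (length(dup))
      problems <- c(problems,
                    paste0("duplicate sample_id: ", paste(dup, collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  for (col in intersect(c("bam", "peaks", "bigwig"), names(samples))) {
    samples[[col]] <- ifelse(is.na(samples[[col]]) | samples[[col]] == "",
                             NA_character_, resolve(samples[[col]]))
    missing <- !is.na(samples[[col]]) & !file.exists(samples[[col]])
    if (any(missing))
      problems <- c(problems, paste0(col, " file not found: ",
                                     paste(samples[[col]][missing],
                                           collapse = ", ")))
  }
  if (!"peak_format" %in% names(samples)) samples$peak_format <- "narrowPeak"
  bad_fmt <- !samples$peak_format %in% c("narrowPeak", "broadPeak", "seacr")
  if (any(bad_fmt))
    problems <- c(problems, paste0("unknown peak_format: ",
                                   paste(unique(samples$peak_format[bad_fmt]),
                                         collapse = ", ")))
  if (!"is_igg" %in% names(samples))
    samples$is_igg <- grepl("igg", samples$sample_id, ignore.case = TRUE)
  samples$is_igg <- as.logical(samples$is_igg)

  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(samples = samples, params = params, path = path),
            class = "run_config")
}

#' Write a run configuration file
#'
#' @param samples data frame with at least \code{sample_id}, \code{bam},
#'   \code{peaks}.
#' @param path output path.
#' @param params named list of parameter overrides written as
#'   \code{#key=value} header lines.
#' @return `path`, invisibly.
#' @export
write_config <- function(samples, path, params = list()) {
  hdr <- if (length(params))
    paste0("#", names(params), "=", vapply(params, as.character, character(1)))
  else character()
  tab <- utils::capture.output(
    utils::write.table(samples, sep = ",", quote = FALSE, row.names = FALSE))
  writeLines(c(hdr, tab), path)
  invisible(path)
}
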