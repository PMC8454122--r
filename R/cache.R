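## Content-addressed result cache: computed objects are stored as RDS files
## named by the MD5 digest of their key (operation name, input file
## signatures, parameters), so reruns with unchanged inputs skip the work.

digest_key <- function(obj) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(obj, f, compress = FALSE)
  unname(tools::md5sum(f))
}

file_sig <- function(path) {
  info <- file.info(path)
  list(name = basename(path), size = unname(info$size),
       mtime = as.numeric(info$mtime))
}

## Run fn() unless cache_dir holds a result for this key.
with_cache <- function(cache_dir, key, fn) {
  if (is.null(cache_dir) || is.na(cache_dir)) return(fn())
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  hit <- file.path(cache_dir, paste0(digest_key(key), ".rds"))
  if (file.exists(hit)) {
    message("cache hit: ", key[[1]], " [", basename(hit), "]")
    return(readRDS(hit))
  }
  res <- fn()
  saveRDS(res, hit)
  res
}
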