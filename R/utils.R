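# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# key=value comment header used by the TSV writers, so that score/count files
# are self-describing and round-trip through the package's own readers
write_meta_header <- function(con, meta) {
  writeLines("# coordinates: 0-based half-open", con)
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.null(v) || length(v) == 0L) next
    writeLines(sprintf("# %s=%s", k, paste(v, collapse = ",")), con)
  }
}

read_meta_header <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- grep("^# ", lines, value = TRUE)
  lines <- grep("=", lines, value = TRUE)
  meta <- list()
  for (ln in lines) {
    ln <- sub("^# ", "", ln)
    k <- sub("=.*$", "", ln)
    meta[[k]] <- sub("^[^=]*=", "", ln)
  }
  meta
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
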