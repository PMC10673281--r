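# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

rms <- function(x) sqrt(mean(x^2))

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# md5-checksummed manifest of files written by a pipeline run
write_manifest <- function(dir, files, extra = list()) {
  files <- files[file.exists(files)]
  man <- tibble::tibble(
    path = basename(files),
    bytes = file.size(files),
    md5 = unname(tools::md5sum(files))
  )
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (length(extra)) {
    jsonlite::write_json(extra, file.path(dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(man)
}
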