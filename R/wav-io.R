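#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the recording format the acoustic pipeline
#' consumes: uncompressed PCM, 16 bits per sample, single channel. Samples are
#' returned full-scale normalized to \eqn{[-1, 1]}.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in \eqn{[-1, 1]}) and
#'   `sample_rate` (Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(riff, "RIFF"), sprintf("'%s' is not a RIFF/WAVE file", path))
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(wave, "WAVE"), sprintf("'%s' is not a RIFF/WAVE file", path))
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no 'data' chunk found in WAV file", call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      assert_that(fmt[1] == 1L, "only uncompressed PCM WAV is supported")
      assert_that(fmt[2] == 1L, "only mono WAV is supported")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little") # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      assert_that(bits == 16L, "only 16-bit PCM WAV is supported")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      assert_that(!is.null(sample_rate), "malformed WAV: 'data' before 'fmt '")
      n <- size %/% 2L
      x <- readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little")
      return(list(samples = x / 32768, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
}

#' Write a mono 16-bit PCM WAV file
#'
#' Samples outside \eqn{[-1, 1]} are clipped; values are quantized to 16 bits.
#'
#' @param samples Numeric vector of amplitudes, nominally in \eqn{[-1, 1]}.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  assert_that(is.numeric(samples) && length(samples) > 0, "`samples` must be a non-empty numeric vector")
  assert_that(all(is.finite(samples)), "`samples` must be finite")
  q <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")          # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
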