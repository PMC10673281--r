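#' Cut a waveform into fixed-length, non-overlapping segments
#'
#' Consecutive segments of `seg_len` seconds are taken from the start of the
#' waveform; a trailing remainder shorter than `seg_len` is discarded. A
#' waveform shorter than one segment yields an empty table (not an error).
#'
#' @param x Numeric vector of samples.
#' @param sample_rate Sampling rate in Hz.
#' @param seg_len Segment length in seconds (default 5 s, the working unit of
#'   the acoustic analysis).
#' @param labels Optional character vector recycled over segments, or `NA`.
#' @return A tibble with columns `segment` (1-based index), `offset_s`,
#'   `label`, `sample_rate`, and `samples` (list-column of numeric vectors).
#' @examples
#' w <- sin(2 * pi * 440 * seq(0, 15, by = 1 / 8000))
#' segment_waveform(w, 8000, seg_len = 5)
#' @export
segment_waveform <- function(x, sample_rate, seg_len = 5, labels = NA_character_) {
  assert_that(is.numeric(x), "`x` must be numeric")
  assert_that(all(is.finite(x)), "`x` must contain finite values only")
  assert_that(sample_rate > 0, "`sample_rate` must be positive")
  assert_that(length(seg_len) == 1 && seg_len > 0, "`seg_len` must be positive")
  spseg <- floor(seg_len * sample_rate)
  n_seg <- length(x) %/% spseg
  if (n_seg == 0) {
    return(tibble::tibble(segment = integer(), offset_s = numeric(),
                          label = character(), sample_rate = numeric(),
                          samples = list()))
  }
  idx <- seq_len(n_seg)
  tibble::tibble(
    segment = idx,
    offset_s = (idx - 1) * spseg / sample_rate,
    label = rep_len(labels, n_seg),
    sample_rate = sample_rate,
    samples = lapply(idx, function(i) x[((i - 1) * spseg + 1):(i * spseg)])
  )
}

#' Normalize audio to unit RMS
#'
#' Scales a waveform so its root-mean-square amplitude is exactly 1, the
#' normalization applied to every segment before feature extraction so that
#' recordings from sensors with different sensitivities are comparable. The
#' operation is idempotent and invariant to positive rescaling of the input.
#'
#' @param x A numeric vector, or a segment table as returned by
#'   [segment_waveform()] (its `samples` column is normalized per segment).
#' @param ... Unused.
#' @return Same shape as the input.
#' @export
rms_normalize <- function(x, ...) UseMethod("rms_normalize")

#' @export
rms_normalize.numeric <- function(x, ...) {
  r <- rms(x)
  assert_that(r > 0, "cannot RMS-normalize an all-zero segment")
  x / r
}

#' @export
rms_normalize.data.frame <- function(x, ...) {
  assert_that("samples" %in% names(x), "segment table must have a `samples` column")
  x$samples <- lapply(x$samples, rms_normalize.numeric)
  x
}

#' One-sided magnitude spectrum of a segment
#'
#' Unwindowed DFT magnitude spectrum from 0 Hz to Nyquist, with bin spacing
#' `sample_rate / length(x)`. Magnitudes are raw DFT magnitudes `|X_k|`;
#' Parseval's relation holds as
#' `sum(x^2) == sum(w * magnitude^2) / length(x)` where `w` doubles every bin
#' except DC and (for even lengths) Nyquist.
#'
#' @param x Numeric vector of samples.
#' @param sample_rate Sampling rate in Hz.
#' @return A tibble with columns `frequency` (Hz, ascending from 0) and
#'   `magnitude` (\eqn{\ge 0}).
#' @export
wave_spectrum <- function(x, sample_rate) {
  assert_that(is.numeric(x) && length(x) > 0, "`x` must be a non-empty numeric vector")
  n <- length(x)
  X <- fft(x)
  n_keep <- floor(n / 2) + 1
  tibble::tibble(
    frequency = (seq_len(n_keep) - 1) * sample_rate / n,
    magnitude = Mod(X[seq_len(n_keep)])
  )
}

# Two-sided power accounting weights for a one-sided spectrum of length n_keep
# derived from an n-point DFT.
one_sided_weights <- function(n) {
  n_keep <- floor(n / 2) + 1
  w <- rep(2, n_keep)
  w[1] <- 1
  if (n %% 2 == 0) w[n_keep] <- 1
  w
}

# FFT-based analytic-signal envelope (Hilbert magnitude).
analytic_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Summary statistics of an audio segment
#'
#' The descriptive statistics used to compare sensor recordings: extreme and
#' mean amplitude, dynamic range, crest factor, and an autocorrelation decay
#' time.
#'
#' Definitions: crest factor is `20*log10(peak / rms)`; dynamic range is the
#' ratio (in dB) of the largest to the smallest nonzero amplitude after
#' quantizing the segment to 16 bits at full scale; the autocorrelation time is
#' the smallest positive lag at which the analytic envelope of the normalized
#' autocorrelation first falls below 0.1 (`NA` if it never does).
#'
#' @param x Numeric vector, or a segment table from [segment_waveform()].
#' @param sample_rate Sampling rate in Hz (ignored for segment tables, which
#'   carry their own).
#' @param ... Unused.
#' @return A tibble with one row per segment and columns `minimum`, `maximum`,
#'   `mean`, `dynamic_range_db`, `crest_factor_db`, `autocorrelation_s`.
#' @export
signal_stats <- function(x, sample_rate, ...) UseMethod("signal_stats")

#' @export
signal_stats.numeric <- function(x, sample_rate, ...) {
  assert_that(length(x) > 0, "segment is empty")
  assert_that(all(is.finite(x)), "segment must be finite")
  peak <- max(abs(x))
  assert_that(peak > 0, "signal statistics are undefined for an all-zero segment")
  q <- abs(round(x / peak * 32767))
  dr <- 20 * log10(max(q) / min(q[q > 0]))
  cf <- 20 * log10(peak / rms(x))
  # normalized autocorrelation via FFT with zero padding
  n <- length(x)
  m <- next_pow2(2 * n)
  X <- fft(c(x, numeric(m - n)))
  r <- Re(fft(X * Conj(X), inverse = TRUE))[seq_len(n)]
  r <- r / r[1]
  env <- analytic_envelope(r)
  below <- which(env < 0.1)
  below <- below[below > 1]
  ac_s <- if (length(below)) (below[1] - 1) / sample_rate else NA_real_
  tibble::tibble(
    minimum = min(x), maximum = max(x), mean = mean(x),
    dynamic_range_db = dr, crest_factor_db = cf, autocorrelation_s = ac_s
  )
}

#' @export
signal_stats.data.frame <- function(x, sample_rate, ...) {
  assert_that(all(c("samples", "sample_rate") %in% names(x)),
              "segment table must have `samples` and `sample_rate` columns")
  dplyr::bind_cols(
    dplyr::select(x, dplyr::any_of(c("segment", "label"))),
    purrr::map2_dfr(x$samples, x$sample_rate, signal_stats.numeric)
  )
}

#' Dominant frequency band of a segment
#'
#' Integrates spectral power inside each activity band and returns the band
#' holding the most power, together with per-band power fractions and the
#' fraction falling outside all bands. This is the band-level characterization
#' of weevil activity (mating 800--950 Hz, pupal movement 1--4 kHz, adult
#' walking 4--5 kHz): a pure 875 Hz tone maps to `mating`, 2 kHz to
#' `pupa_moving`, 4.5 kHz to `adult_walking`.
#'
#' @param x Numeric vector, or a segment table from [segment_waveform()].
#' @param sample_rate Sampling rate in Hz.
#' @param bands Band table from [band_scheme()].
#' @param ... Unused.
#' @return A tibble with one row per segment: `band` (activity name of the
#'   winning band), one `frac_<activity>` column per band, and
#'   `out_of_band` (power fraction outside all bands).
#' @export
dominant_band <- function(x, sample_rate, bands = band_scheme(), ...) UseMethod("dominant_band")

#' @export
dominant_band.numeric <- function(x, sample_rate, bands = band_scheme(), ...) {
  validate_bands(bands, sample_rate)
  n <- length(x)
  spec <- wave_spectrum(x, sample_rate)
  p <- one_sided_weights(n) * spec$magnitude^2
  total <- sum(p)
  frac <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- spec$frequency >= bands$f_lo[i] & spec$frequency <= bands$f_hi[i]
    if (total > 0) sum(p[sel]) / total else 0
  }, numeric(1))
  out <- tibble::tibble(band = bands$activity[which.max(frac)])
  for (i in seq_len(nrow(bands))) out[[paste0("frac_", bands$activity[i])]] <- frac[i]
  out$out_of_band <- max(0, 1 - sum(frac))
  out
}

#' @export
dominant_band.data.frame <- function(x, sample_rate, bands = band_scheme(), ...) {
  assert_that(all(c("samples", "sample_rate") %in% names(x)),
              "segment table must have `samples` and `sample_rate` columns")
  dplyr::bind_cols(
    dplyr::select(x, dplyr::any_of(c("segment", "label"))),
    purrr::map2_dfr(x$samples, x$sample_rate, dominant_band.numeric, bands = bands)
  )
}
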