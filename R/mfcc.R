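#' Hz to Mel conversion
#'
#' The conventional Mel mapping `2595 * log10(1 + f / 700)`: approximately
#' linear below ~1 kHz and logarithmic above. Strictly increasing and exactly
#' inverted by [mel_to_hz()].
#'
#' @param f Frequencies in Hz (non-negative).
#' @return Mel values.
#' @export
hz_to_mel <- function(f) {
  assert_that(all(f >= 0), "frequencies must be non-negative")
  2595 * log10(1 + f / 700)
}

#' Mel to Hz conversion
#'
#' @param m Mel values (non-negative).
#' @return Frequencies in Hz.
#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) {
  assert_that(all(m >= 0), "Mel values must be non-negative")
  700 * (10^(m / 2595) - 1)
}

#' MFCC front-end configuration
#'
#' Framing, windowing, filter-bank and DCT parameters for the cepstral
#' feature extractor. Defaults are the conventional speech/bioacoustics
#' choices: 25 ms frames with 10 ms hop, Hamming window, FFT length the next
#' power of two at or above the frame length, 26 triangular Mel filters
#' spanning 0 Hz to Nyquist, 13 retained coefficients, and a floor of 1e-10
#' on filter-bank energies before the logarithm.
#'
#' @param sample_rate Sampling rate in Hz the configuration is built for.
#' @param frame_length Frame length in samples (default: 25 ms worth).
#' @param hop Hop between frame starts in samples (default: 10 ms worth).
#' @param window One of `"hamming"`, `"hann"`, `"rect"`.
#' @param n_fft FFT length in samples; must be at least `frame_length`.
#' @param n_mel_filters Number of triangular Mel filters.
#' @param n_coefficients Number of cepstral coefficients retained
#'   (`<= n_mel_filters`).
#' @param f_min,f_max Filter-bank frequency range in Hz (`f_max <= Nyquist`).
#' @param log_floor Positive floor applied to filter-bank energies before the
#'   log, keeping silent frames finite.
#' @return An object of class `mfcc_config`.
#' @examples
#' mfcc_config(44100)
#' @export
mfcc_config <- function(sample_rate,
                        frame_length = round(0.025 * sample_rate),
                        hop = round(0.010 * sample_rate),
                        window = c("hamming", "hann", "rect"),
                        n_fft = next_pow2(frame_length),
                        n_mel_filters = 26,
                        n_coefficients = 13,
                        f_min = 0,
                        f_max = sample_rate / 2,
                        log_floor = 1e-10) {
  window <- match.arg(window)
  assert_that(sample_rate > 0, "`sample_rate` must be positive")
  assert_that(is_count(frame_length) && is_count(hop) && is_count(n_fft),
              "frame_length, hop and n_fft must be positive integers")
  assert_that(hop <= frame_length && frame_length <= n_fft,
              "need hop <= frame_length <= n_fft")
  assert_that(is_count(n_mel_filters) && is_count(n_coefficients) &&
                n_coefficients <= n_mel_filters,
              "need 0 < n_coefficients <= n_mel_filters")
  assert_that(f_min >= 0 && f_min < f_max && f_max <= sample_rate / 2,
              "need 0 <= f_min < f_max <= sample_rate / 2")
  assert_that(length(log_floor) == 1 && log_floor > 0, "`log_floor` must be positive")
  structure(list(
    sample_rate = sample_rate, frame_length = as.integer(frame_length),
    hop = as.integer(hop), window = window, n_fft = as.integer(n_fft),
    n_mel_filters = as.integer(n_mel_filters),
    n_coefficients = as.integer(n_coefficients),
    f_min = f_min, f_max = f_max, log_floor = log_floor
  ), class = "mfcc_config")
}

#' @export
print.mfcc_config <- function(x, ...) {
  cat(sprintf(
    "<mfcc_config> sr %g Hz | frame %d hop %d n_fft %d (%s) | %d mel filters %g-%g Hz | %d coefs\n",
    x$sample_rate, x$frame_length, x$hop, x$n_fft, x$window,
    x$n_mel_filters, x$f_min, x$f_max, x$n_coefficients))
  invisible(x)
}

window_vector <- function(window, n) {
  k <- seq_len(n) - 1
  switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
    rect = rep(1, n)
  )
}

# Orthonormal DCT-II matrix mapping M filter-bank log-energies to n_out
# coefficients (rows are basis vectors).
dct2_matrix <- function(n_out, M) {
  k <- seq_len(n_out) - 1
  n <- seq_len(M) - 1
  D <- sqrt(2 / M) * cos(pi * outer(k, 2 * n + 1) / (2 * M))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Triangular Mel-spaced filter bank
#'
#' Builds `n_mel_filters` triangular filters whose edges and centers are the
#' `n_mel_filters + 2` points uniformly spaced on the Mel scale between
#' `f_min` and `f_max`, snapped to FFT bins. Each filter peaks with weight 1
#' at its own center bin; filters `k` and `k + 2` have disjoint support.
#'
#' @param cfg An [mfcc_config()].
#' @return An object of class `mel_filterbank`: list with `weights`
#'   (`n_mel_filters` x `n_fft/2 + 1` non-negative matrix), `centers_hz`, and
#'   `bin_freq` (Hz of each FFT bin).
#' @export
mel_filterbank <- function(cfg) {
  assert_that(inherits(cfg, "mfcc_config"), "`cfg` must be an mfcc_config")
  n_bins <- cfg$n_fft %/% 2 + 1
  df <- cfg$sample_rate / cfg$n_fft
  mels <- seq(hz_to_mel(cfg$f_min), hz_to_mel(cfg$f_max), length.out = cfg$n_mel_filters + 2)
  pts <- pmin(round(mel_to_hz(mels) / df), n_bins - 1)  # 0-based bin indices
  assert_that(!anyDuplicated(pts),
              "too many Mel filters for the FFT resolution (duplicate bin centers)")
  W <- matrix(0, cfg$n_mel_filters, n_bins)
  for (m in seq_len(cfg$n_mel_filters)) {
    lo <- pts[m]; ce <- pts[m + 1]; hi <- pts[m + 2]
    rise <- lo:ce
    W[m, rise + 1] <- (rise - lo) / (ce - lo)
    fall <- ce:hi
    W[m, fall + 1] <- (hi - fall) / (hi - ce)
    W[m, ce + 1] <- 1
  }
  structure(list(weights = W, centers_hz = pts[2:(cfg$n_mel_filters + 1)] * df,
                 bin_freq = (seq_len(n_bins) - 1) * df),
            class = "mel_filterbank")
}

# Shared front half of the cepstral pipeline: framing -> window -> power
# spectrum -> Mel filter-bank log-energies. Returns frames x n_mel matrix.
mel_log_energies <- function(x, cfg, fb = mel_filterbank(cfg)) {
  assert_that(is.numeric(x), "`x` must be numeric")
  n <- length(x)
  assert_that(n >= cfg$frame_length,
              "segment is shorter than one analysis frame")
  n_frames <- (n - cfg$frame_length) %/% cfg$hop + 1
  idx <- outer(seq_len(cfg$frame_length), (seq_len(n_frames) - 1) * cfg$hop, "+")
  frames <- matrix(x[idx], cfg$frame_length, n_frames) * window_vector(cfg$window, cfg$frame_length)
  if (cfg$n_fft > cfg$frame_length) {
    frames <- rbind(frames, matrix(0, cfg$n_fft - cfg$frame_length, n_frames))
  }
  P <- Mod(mvfft(frames)[seq_len(cfg$n_fft %/% 2 + 1), , drop = FALSE])^2
  E <- fb$weights %*% P
  logE <- t(log(pmax(E, cfg$log_floor)))
  attr(logE, "times") <- ((seq_len(n_frames) - 1) * cfg$hop + cfg$frame_length / 2) / cfg$sample_rate
  logE
}

#' Mel-frequency cepstral coefficients of a segment
#'
#' Per frame: window, magnitude-squared spectrum, triangular Mel filter-bank
#' energies, log compression (floored at `log_floor`), orthonormal DCT-II,
#' first `n_coefficients` retained. The first coefficient tracks overall
#' log-energy; higher coefficients describe the spectral envelope shape.
#'
#' @param x Numeric vector of samples (at least one frame long).
#' @param cfg An [mfcc_config()].
#' @return A `frames x n_coefficients` matrix of class `mfcc_matrix`, with a
#'   `times` attribute giving each frame's center time in seconds.
#' @seealso [mel_spectrogram()], [mfcc_features()]
#' @export
mfcc <- function(x, cfg) {
  logE <- mel_log_energies(x, cfg)
  D <- dct2_matrix(cfg$n_coefficients, cfg$n_mel_filters)
  out <- logE %*% t(D)
  colnames(out) <- sprintf("c%02d", seq_len(cfg$n_coefficients) - 1)
  attr(out, "times") <- attr(logE, "times")
  class(out) <- c("mfcc_matrix", class(out))
  out
}

#' Log-Mel spectrogram of a segment
#'
#' The filter-bank log-energies before the DCT; the DCT of its rows
#' reproduces [mfcc()] output exactly.
#'
#' @inheritParams mfcc
#' @return A `frames x n_mel_filters` matrix of class `mel_spectrogram` with
#'   attributes `times` (s) and `centers_hz` (filter center frequencies).
#' @export
mel_spectrogram <- function(x, cfg) {
  fb <- mel_filterbank(cfg)
  logE <- mel_log_energies(x, cfg, fb)
  attr(logE, "centers_hz") <- fb$centers_hz
  class(logE) <- c("mel_spectrogram", class(logE))
  logE
}

#' Per-segment aggregate MFCC features
#'
#' Collapses each segment's coefficient trajectories to their mean and
#' standard deviation across frames, the fixed-length feature vector consumed
#' by the activity classifier (2 x `n_coefficients` features per segment).
#'
#' @param segments A segment table from [segment_waveform()] (columns
#'   `segment`, `label`, `sample_rate`, `samples`).
#' @param cfg An [mfcc_config()]; defaults to `mfcc_config()` at the table's
#'   sampling rate.
#' @param normalize RMS-normalize each segment first (default `TRUE`).
#' @return A tibble: `segment`, `label`, then `c<k>_mean` and `c<k>_sd`
#'   columns.
#' @export
mfcc_features <- function(segments, cfg = NULL, normalize = TRUE) {
  assert_that(is.data.frame(segments) && nrow(segments) > 0,
              "`segments` must be a non-empty segment table")
  if (is.null(cfg)) cfg <- mfcc_config(segments$sample_rate[1])
  fb <- mel_filterbank(cfg)
  D <- dct2_matrix(cfg$n_coefficients, cfg$n_mel_filters)
  rows <- purrr::map(segments$samples, function(s) {
    if (normalize) s <- rms_normalize.numeric(s)
    C <- mel_log_energies(s, cfg, fb) %*% t(D)
    stats_row(C)
  })
  dplyr::bind_cols(
    dplyr::select(segments, dplyr::any_of(c("segment", "label"))),
    dplyr::bind_rows(rows)
  )
}

stats_row <- function(C) {
  mu <- colMeans(C)
  s <- apply(C, 2, sd)
  if (nrow(C) == 1) s[] <- 0
  out <- c(mu, s)
  names(out) <- c(sprintf("c%02d_mean", seq_along(mu) - 1),
                  sprintf("c%02d_sd", seq_along(s) - 1))
  tibble::as_tibble(as.list(out))
}
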