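# Independent oracles and small fixture builders used across the suite.

make_sine <- function(freq, sr, dur = 1, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, dur - 1 / sr, by = 1 / sr) + phase)
}

# Naive O(n^2) one-sided DFT magnitudes, written directly from the Fourier sum.
naive_dft_magnitude <- function(x) {
  n <- length(x)
  ks <- 0:(floor(n / 2))
  vapply(ks, function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))
  }, numeric(1))
}

# Brute-force Otsu: evaluate the between-class variance of every split
# s in 1..255 (classes {< s} and {>= s}) by direct computation on the pixel
# vector, and return the smallest maximizer.
otsu_oracle <- function(frame) {
  v <- as.integer(frame)
  best_s <- NA_integer_
  best_var <- -Inf
  for (s in 1:255) {
    lo <- v[v < s]
    hi <- v[v >= s]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best_var + 1e-12) {
      best_var <- sb
      best_s <- s
    }
  }
  best_s
}

# Independently coded, loop-based MFCC: own framing, own DFT, own Mel
# triangles, own DCT. Deliberately slow and literal.
naive_mfcc <- function(x, cfg) {
  n_frames <- (length(x) - cfg$frame_length) %/% cfg$hop + 1
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(cfg$frame_length - 1)) / (cfg$frame_length - 1))
  n_bins <- cfg$n_fft %/% 2 + 1
  df <- cfg$sample_rate / cfg$n_fft
  mel_pts <- seq(2595 * log10(1 + cfg$f_min / 700), 2595 * log10(1 + cfg$f_max / 700),
                 length.out = cfg$n_mel_filters + 2)
  hz_pts <- 700 * (10^(mel_pts / 2595) - 1)
  bin_pts <- pmin(round(hz_pts / df), n_bins - 1)
  out <- matrix(0, n_frames, cfg$n_coefficients)
  for (f in seq_len(n_frames)) {
    fr <- x[((f - 1) * cfg$hop + 1):((f - 1) * cfg$hop + cfg$frame_length)] * w
    fr <- c(fr, numeric(cfg$n_fft - cfg$frame_length))
    P <- numeric(n_bins)
    for (k in 0:(n_bins - 1)) {
      P[k + 1] <- Mod(sum(fr * exp(-2i * pi * k * (0:(cfg$n_fft - 1)) / cfg$n_fft)))^2
    }
    logE <- numeric(cfg$n_mel_filters)
    for (m in seq_len(cfg$n_mel_filters)) {
      lo <- bin_pts[m]; ce <- bin_pts[m + 1]; hi <- bin_pts[m + 2]
      e <- 0
      for (k in lo:hi) {
        wt <- if (k < ce) (k - lo) / (ce - lo) else if (k > ce) (hi - k) / (hi - ce) else 1
        e <- e + wt * P[k + 1]
      }
      logE[m] <- log(max(e, cfg$log_floor))
    }
    for (cc in 0:(cfg$n_coefficients - 1)) {
      acc <- 0
      for (m in 0:(cfg$n_mel_filters - 1)) {
        acc <- acc + logE[m + 1] * cos(pi * cc * (2 * m + 1) / (2 * cfg$n_mel_filters))
      }
      scale <- if (cc == 0) sqrt(1 / cfg$n_mel_filters) else sqrt(2 / cfg$n_mel_filters)
      out[f, cc + 1] <- scale * acc
    }
  }
  out
}

# A quick two-blob synthetic scene for video tests (small frames, fast).
tiny_video_scenario <- function(mating_s, seed = 1, chase_s = 3, separate_s = 3) {
  video_scenario(chase_s = chase_s, mating_s = mating_s, separate_s = separate_s,
                 fps = 10, seed = seed)
}
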