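test_that("Mel scale conversions are exact and mutually inverse", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  for (f in c(100, 1000, 8000)) {
    expect_equal(mel_to_hz(hz_to_mel(f)), f, tolerance = 1e-9)
  }
  expect_true(all(diff(hz_to_mel(seq(0, 10000, by = 50))) > 0))
  expect_error(hz_to_mel(-1), "non-negative")
  expect_error(mel_to_hz(-1), "non-negative")
})

test_that("filter bank is triangular, Mel-uniform and resolution-checked", {
  cfg <- mfcc_config(16000, frame_length = 400, hop = 160, n_fft = 512,
                     n_mel_filters = 20)
  fb <- mel_filterbank(cfg)
  expect_equal(dim(fb$weights), c(20, 257))
  expect_true(all(fb$weights >= 0))

  # centers uniform on the Mel scale within one bin's Mel width
  df <- 16000 / 512
  mels <- seq(hz_to_mel(cfg$f_min), hz_to_mel(cfg$f_max), length.out = 22)
  for (m in 1:20) {
    tol <- hz_to_mel(fb$centers_hz[m] + df) - hz_to_mel(max(fb$centers_hz[m] - df, 0))
    expect_lt(abs(hz_to_mel(fb$centers_hz[m]) - mels[m + 1]), tol)
  }

  # the center bin carries the filter maximum (weight 1)
  center_bins <- round(fb$centers_hz / df) + 1
  for (m in 1:20) {
    expect_equal(fb$weights[m, center_bins[m]], 1)
    expect_equal(max(fb$weights[m, ]), 1)
  }

  # filters k and k + 2 have disjoint support
  for (m in 1:18) {
    expect_equal(sum(fb$weights[m, ] > 0 & fb$weights[m + 2, ] > 0), 0)
  }

  expect_error(mel_filterbank(mfcc_config(16000, frame_length = 64, hop = 32,
                                          n_fft = 64, n_mel_filters = 40,
                                          n_coefficients = 13)),
               "duplicate bin centers")
})

test_that("MFCC framing, degenerate inputs and polarity behave as specified", {
  cfg <- mfcc_config(44100)
  m <- mfcc(rnorm(44100), cfg)
  expect_equal(nrow(m), (44100 - 1102) %/% 441 + 1)  # 98 frames
  expect_equal(ncol(m), 13)

  cfg8 <- mfcc_config(8000)
  z <- mfcc(numeric(8000), cfg8)
  expect_true(all(apply(z, 2, function(col) max(col) - min(col)) < 1e-12))

  x <- rnorm(8000)
  expect_equal(unclass(mfcc(x, cfg8)), unclass(mfcc(-x, cfg8)))
})

test_that("a tone at a filter center dominates that filter and c0 grows with gain", {
  cfg <- mfcc_config(16000, n_mel_filters = 20)
  fb <- mel_filterbank(cfg)
  target <- 10
  x <- make_sine(fb$centers_hz[target], 16000, dur = 0.5)
  spec <- mel_spectrogram(x, cfg)
  expect_equal(unname(which.max(colMeans(spec))), target)

  c0 <- vapply(c(0.1, 1, 10), function(g) mean(mfcc(g * x, cfg)[, 1]), numeric(1))
  expect_true(all(diff(c0) > 0))
})

test_that("DCT-II is orthonormal and the spectrogram pipeline is consistent", {
  D <- weevilsense:::dct2_matrix(26, 26)
  expect_equal(D %*% t(D), diag(26), tolerance = 1e-9)
  v <- rnorm(26)
  expect_equal(as.vector(t(D) %*% (D %*% v)), v, tolerance = 1e-9)

  cfg <- mfcc_config(8000, n_mel_filters = 20, n_coefficients = 8)
  x <- rnorm(4000)
  spec <- mel_spectrogram(x, cfg)
  D8 <- weevilsense:::dct2_matrix(8, 20)
  expect_equal(unclass(mfcc(x, cfg)),
               unclass(unclass(spec) %*% t(D8)) ,
               ignore_attr = TRUE)
})

test_that("adult-band synthetic audio peaks in a 4-5 kHz Mel filter", {
  sc <- audio_scenario(segment_length = 1, segments_per_class = 1,
                       snr_db = 30, seed = 9)
  scene <- generate_audio(sc, classes = "adult_walking")
  cfg <- mfcc_config(44100)
  fb <- mel_filterbank(cfg)
  spec <- mel_spectrogram(rms_normalize(scene$segments$samples[[1]]), cfg)
  peak_center <- fb$centers_hz[which.max(colMeans(spec))]
  expect_gte(peak_center, 4000)
  expect_lte(peak_center, 5000)
})

test_that("implementation agrees with an independently coded literal MFCC", {
  cfg <- mfcc_config(8000, frame_length = 64, hop = 32, n_fft = 64,
                     n_mel_filters = 10, n_coefficients = 5)
  set.seed(21)
  for (i in 1:3) {
    x <- rnorm(320)
    mine <- unclass(mfcc(x, cfg))
    ref <- naive_mfcc(x, cfg)
    expect_gt(cor(as.vector(mine), as.vector(ref), method = "spearman"), 0.99)
    expect_equal(unname(mine), ref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})
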