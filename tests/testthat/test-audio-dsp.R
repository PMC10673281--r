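test_that("segmentation cuts non-overlapping 5-s windows and drops the remainder", {
  sr <- 8000
  x <- rnorm(15 * sr)
  segs <- segment_waveform(x, sr, seg_len = 5)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$offset_s, c(0, 5, 10))
  expect_identical(unlist(segs$samples), x[1:(15 * sr)])

  segs2 <- segment_waveform(rnorm(14.9 * sr), sr, seg_len = 5)
  expect_equal(nrow(segs2), 2)

  expect_equal(nrow(segment_waveform(rnorm(100), sr, seg_len = 5)), 0)
})

test_that("RMS normalization reaches unit RMS, is idempotent and scale-invariant", {
  sr <- 8000
  s <- make_sine(100, sr, amp = 0.2)
  n1 <- rms_normalize(s)
  expect_equal(sqrt(mean(n1^2)), 1, tolerance = 1e-9)
  expect_equal(max(abs(n1)), sqrt(2), tolerance = 1e-6)
  expect_equal(rms_normalize(n1), n1, tolerance = 1e-9)
  expect_equal(rms_normalize(3.7 * s), n1, tolerance = 1e-9)
  expect_equal(rms_normalize(rep(0.42, 100)), rep(1, 100))
  expect_error(rms_normalize(numeric(64)), "all-zero")
})

test_that("spectrum matches the naive DFT oracle and Parseval's relation", {
  set.seed(11)
  for (i in 1:3) {
    x <- rnorm(256)
    spec <- wave_spectrum(x, 256)
    expect_equal(spec$magnitude, naive_dft_magnitude(x),
                 tolerance = 1e-8)
    # Parseval: time-domain energy equals weighted one-sided spectral power
    w <- weevilsense:::one_sided_weights(length(x))
    expect_equal(sum(x^2), sum(w * spec$magnitude^2) / length(x),
                 tolerance = 1e-6)
  }
  s <- wave_spectrum(make_sine(1000, 8000), 8000)
  expect_equal(s$frequency[which.max(s$magnitude)], 1000)
  expect_true(all(wave_spectrum(numeric(64), 64)$magnitude == 0))
})

test_that("signal statistics reproduce closed-form crest factors", {
  sr <- 8000
  st <- signal_stats(make_sine(100, sr), sr)
  expect_equal(st$crest_factor_db, 20 * log10(sqrt(2)), tolerance = 0.05)

  square <- rep(c(0.5, -0.5), each = 40, times = 100)
  expect_equal(signal_stats(square, sr)$crest_factor_db, 0, tolerance = 1e-9)

  N <- 256
  imp <- c(1, numeric(N - 1))
  expect_equal(signal_stats(imp, sr)$crest_factor_db, 20 * log10(sqrt(N)),
               tolerance = 1e-9)

  expect_error(signal_stats(numeric(100), sr), "all-zero")
  expect_true(st$maximum >= st$mean && st$mean >= st$minimum)
  expect_true(st$dynamic_range_db >= 0)
})

test_that("pure tones land in their activity bands and the call is normalization-invariant", {
  sr <- 44100
  cases <- list(c(4500, NA), c(875, NA), c(2000, NA))
  expected <- c("adult_walking", "mating", "pupa_moving")
  for (i in seq_along(cases)) {
    x <- make_sine(cases[[i]][1], sr, dur = 0.5)
    db <- dominant_band(x, sr)
    expect_equal(db$band, expected[i])
    expect_equal(dominant_band(rms_normalize(x), sr)$band, expected[i])
  }
})

test_that("WAV files round-trip through the 16-bit reader/writer", {
  set.seed(5)
  x <- runif(4000, -0.9, 0.9)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 8000, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 8000)
  expect_equal(back$samples, x, tolerance = 1 / 32767 * 2)
})
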