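# Synthetic audio scenes -----------------------------------------------------

test_that("noise-free segments are confined to their class band", {
  sc <- audio_scenario(segment_length = 1, segments_per_class = 2,
                       snr_db = Inf, seed = 4)
  scene <- generate_audio(sc, classes = "mating")
  db <- dominant_band(scene$segments)
  expect_true(all(db$frac_mating >= 0.95))
  expect_true(all(db$band == "mating"))
})

test_that("audio generation is deterministic under the seed, down to WAV bytes", {
  sc <- audio_scenario(sample_rate = 16000, segment_length = 0.5,
                       segments_per_class = 2, snr_db = 20, seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_audio(sc, dir = d1)
  s2 <- generate_audio(sc, dir = d2)
  expect_identical(s1$segments$samples, s2$segments$samples)
  expect_identical(readBin(file.path(d1, "scene.wav"), "raw", 1e6),
                   readBin(file.path(d2, "scene.wav"), "raw", 1e6))
  expect_identical(readLines(file.path(d1, "labels.csv")),
                   readLines(file.path(d2, "labels.csv")))
})

test_that("in-band power fraction degrades with SNR", {
  frac_at <- function(snr) {
    sc <- audio_scenario(segment_length = 1, segments_per_class = 1,
                         snr_db = snr, seed = 8)
    scene <- generate_audio(sc, classes = "adult_walking")
    dominant_band(scene$segments)$frac_adult_walking
  }
  expect_lt(frac_at(0), frac_at(30))
})

test_that("label files conserve counts and the scene validates its inputs", {
  sc <- audio_scenario(sample_rate = 16000, segment_length = 5,
                       segments_per_class = 12, snr_db = 30, seed = 2)
  scene <- generate_audio(sc)
  expect_equal(nrow(scene$labels), 12 * 4)
  expect_equal(as.vector(table(scene$labels$label)), rep(12, 4))
  expect_equal(scene$labels$end_s - scene$labels$start_s, rep(5, 48))

  # band edge at/above Nyquist is a configuration error
  expect_error(generate_audio(audio_scenario(sample_rate = 8000, seed = 1)),
               "Nyquist")
  expect_error(audio_scenario(segments_per_class = 0), "positive integer")
})

test_that("resting segments are noise at the SNR-implied level", {
  sc <- audio_scenario(sample_rate = 16000, segment_length = 1,
                       segments_per_class = 3, snr_db = 30, seed = 6)
  scene <- generate_audio(sc, classes = "resting")
  expected_rms <- 0.05 / 10^(30 / 20)
  for (x in scene$segments$samples) {
    expect_equal(sqrt(mean(x^2)), expected_rms, tolerance = 0.05)
  }
  # noise-free scenes still produce nonzero resting audio
  scn <- generate_audio(audio_scenario(sample_rate = 16000, segment_length = 1,
                                       segments_per_class = 1, snr_db = Inf,
                                       seed = 6), classes = "resting")
  expect_gt(sqrt(mean(scn$segments$samples[[1]]^2)), 0)
})

# Synthetic videos ------------------------------------------------------------

test_that("video ground truth follows the phase script exactly", {
  vs <- video_scenario(chase_s = 10, mating_s = 10, separate_s = 5,
                       fps = 10, seed = 3)
  expect_equal(vs$script$start_frame, c(0, 100, 200))
  expect_equal(vs$script$end_frame, c(100, 200, 250))
  scene <- generate_video(vs)
  expect_equal(scene$ground_truth$event_start_s, 10)
  expect_equal(scene$ground_truth$event_end_s - scene$ground_truth$event_start_s, 10)

  none <- generate_video(video_scenario(chase_s = 2, mating_s = 0,
                                        separate_s = 1, seed = 3))
  expect_equal(nrow(none$ground_truth), 0)
})

test_that("overlap frames contain one merged weevil component plus the mango", {
  scene <- generate_video(tiny_video_scenario(mating_s = 4, seed = 5))
  ov_frame <- scene$frames[[45]]  # middle of overlap phase [30, 70)
  blobs_all <- detect_blobs(ov_frame)
  expect_equal(nrow(blobs_all), 2)  # merged pair + mango
  single_area <- pi * 9 * 6
  in_window <- detect_blobs(ov_frame, area_window = single_area * c(0.5, 3))
  expect_equal(nrow(in_window), 1)

  chase_frame <- scene$frames[[5]]
  expect_equal(nrow(detect_blobs(chase_frame, area_window = single_area * c(0.5, 3))), 2)
})

test_that("video generation is deterministic and scripts validate ordering", {
  vs <- tiny_video_scenario(mating_s = 2, seed = 10)
  expect_identical(generate_video(vs)$frames, generate_video(vs)$frames)

  bad <- tibble::tibble(phase = c("overlap", "chase"),
                        start_frame = c(0, 20), end_frame = c(20, 40))
  expect_error(video_scenario(script = bad), "out of order")
  gap <- tibble::tibble(phase = c("chase", "overlap"),
                        start_frame = c(0, 30), end_frame = c(20, 40))
  expect_error(video_scenario(script = gap), "contiguous")
})

test_that("frame directories round-trip through PGM with fps metadata", {
  scene <- generate_video(video_scenario(chase_s = 0.5, mating_s = 0,
                                         separate_s = 0, seed = 1))
  dir <- withr::local_tempdir()
  write_frames(scene, dir, format = "pgm")
  back <- read_frames(dir)
  expect_equal(back$fps, 10)
  expect_identical(back$frames, scene$frames)
})
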