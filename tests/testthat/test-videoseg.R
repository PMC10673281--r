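test_that("Otsu picks the smallest separating split on bimodal frames", {
  f <- matrix(rep(c(50L, 200L), each = 200), 20, 20)
  t <- otsu_threshold(f)
  expect_true(all(f[f < t] == 50) && all(f[f >= t] == 200))
  expect_equal(t, otsu_oracle(f))
  expect_error(otsu_threshold(matrix(7L, 4, 4)), "constant")
})

test_that("Otsu equals the exhaustive-search oracle, also on inverted frames", {
  set.seed(31)
  for (i in 1:20) {
    f <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
    expect_identical(otsu_threshold(f), otsu_oracle(f))
    inv <- 255L - f
    expect_identical(otsu_threshold(inv), otsu_oracle(inv))
  }
})

test_that("blob detection filters by area window and handles blank frames", {
  f <- matrix(255L, 40, 60)
  f[5:8, 5:8] <- 10L          # 16 px blob
  f[20:29, 20:39] <- 10L      # 200 px region
  b <- detect_blobs(f, threshold = 100, area_window = c(10, 50))
  expect_equal(nrow(b), 1)
  expect_equal(b$area, 16)
  expect_equal(b$row, mean(4:7))  # 0-based centroid
  expect_equal(c(b$top, b$left, b$bottom, b$right), c(4, 4, 8, 8))

  expect_equal(nrow(detect_blobs(f, threshold = 100, area_window = c(1, Inf))), 2)
  expect_equal(nrow(detect_blobs(matrix(255L, 10, 10), threshold = 100)), 0)
})

test_that("8-connectivity joins diagonally touching pixels", {
  f <- matrix(255L, 10, 10)
  f[cbind(c(2, 3, 4), c(2, 3, 4))] <- 0L  # diagonal line
  b <- detect_blobs(f, threshold = 100)
  expect_equal(nrow(b), 1)
  expect_equal(b$area, 3)
})

test_that("distance gating rejects jumps and matches exhaustive 2x2 assignment", {
  preds <- rbind(c(0, 0), c(0, 3))
  expect_equal(gate_by_distance(preds[1, , drop = FALSE], rbind(c(0, 0)), 5), 1L)
  expect_equal(gate_by_distance(preds, rbind(c(100, 100)), 5), NA_integer_)

  # two candidates, two tracks: compare with brute-force minimal total distance
  cands <- rbind(c(0, 1), c(0, 10))
  d <- function(a, b) sqrt(sum((a - b)^2))
  straight <- d(cands[1, ], preds[1, ]) + d(cands[2, ], preds[2, ])
  crossed <- d(cands[1, ], preds[2, ]) + d(cands[2, ], preds[1, ])
  best <- if (straight <= crossed) c(1L, 2L) else c(2L, 1L)
  expect_equal(gate_by_distance(preds, cands, 20), best)

  # a greedy nearest-first pairing (c1 to t2, then c2 forced to t1) would be
  # suboptimal here; the exhaustive assignment takes the straight pairing
  preds2 <- rbind(c(0, 0), c(0, 4))
  cands2 <- rbind(c(0, 3), c(0, 5))
  expect_equal(gate_by_distance(preds2, cands2, 20), c(1L, 2L))
})

test_that("the constant-velocity Kalman filter recovers exact tracks", {
  tr <- kalman_track(c(0, 0), process_noise = 0, measurement_noise = 0)
  for (k in 1:10) {
    tr <- kalman_step(tr, c(k, 2 * k))
    if (k >= 3) {
      expect_equal(tr$x[1:2], c(k, 2 * k), tolerance = 1e-9)
      expect_equal(tr$x[3:4], c(1, 2), tolerance = 1e-9)
    }
  }

  tr2 <- kalman_track(c(0, 0), process_noise = 0, measurement_noise = 0)
  for (k in 1:6) tr2 <- kalman_step(tr2, c(5, 5))
  expect_equal(tr2$x[1:2], c(5, 5), tolerance = 1e-9)

  # predict-only: position advances by exactly one velocity increment
  tr3 <- kalman_track(c(10, 20), velocity = c(2, -3))
  tr3 <- kalman_step(tr3, NULL)
  expect_identical(tr3$x[1:2], c(12, 17))
  expect_equal(tr3$misses, 1L)
  expect_error(kalman_step(tr3, c(NaN, 1)), "finite")
})

test_that("box overlap uses the half-open convention", {
  r <- overlap_boxes(c(0, 0, 10, 10), c(5, 5, 15, 15))
  expect_true(r$overlap)
  expect_equal(r$iou, 25 / 175)
  expect_false(overlap_boxes(c(0, 0, 10, 10), c(0, 10, 10, 20))$overlap)
  expect_equal(overlap_boxes(c(0, 0, 10, 10), c(0, 0, 10, 10))$iou, 1)
  expect_error(overlap_boxes(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
})

test_that("event extraction respects the persistence rule", {
  eff <- weevilsense:::events_from_flags
  # scripted overlap frames [100, 199] at 10 fps (0-based)
  flags <- c(rep(FALSE, 100), rep(TRUE, 100), rep(FALSE, 50))
  ev <- eff(flags, fps = 10, k_persist = 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 10)
  expect_equal(ev$duration_s, 10)

  # single-frame flicker neither starts nor ends an event
  expect_equal(nrow(eff(c(rep(FALSE, 10), TRUE, rep(FALSE, 10)), 10, 3)), 0)
  mid_flicker <- c(rep(FALSE, 10), rep(TRUE, 10), FALSE, rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(nrow(eff(mid_flicker, 10, 3)), 1)
})

test_that("scripted videos segment into the scripted mating event", {
  scene <- generate_video(tiny_video_scenario(mating_s = 6, seed = 7))
  ev <- segment_mating(scene)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 3, tolerance = 0.35)
  expect_equal(ev$duration_s, 6, tolerance = 0.45)
  expect_true(all(ev$end_s > ev$start_s))
  expect_lte(sum(ev$duration_s), length(scene$frames) / 10)

  none <- generate_video(tiny_video_scenario(mating_s = 0, seed = 7))
  expect_equal(nrow(segment_mating(none)), 0)
})
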