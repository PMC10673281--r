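#' Otsu intensity threshold of a grayscale frame
#'
#' Exhaustively evaluates all 256-bin histogram splits and returns the
#' threshold `t` maximizing the between-class variance, with ties broken
#' toward the smallest `t`. The convention is half-open: pixels with
#' intensity strictly below `t` form one class (the dark foreground used by
#' [detect_blobs()]), pixels at or above `t` the other.
#'
#' @param frame Integer/numeric matrix of intensities in `[0, 255]`.
#' @return The optimal threshold (integer in `[1, 255]`).
#' @export
otsu_threshold <- function(frame) {
  assert_that(is.matrix(frame), "`frame` must be a matrix")
  v <- as.integer(frame)
  assert_that(all(v >= 0 & v <= 255), "intensities must lie in [0, 255]")
  assert_that(length(unique(v)) >= 2, "cannot threshold a constant frame")
  counts <- tabulate(v + 1L, nbins = 256)
  n <- length(v)
  csum <- cumsum(counts)
  msum <- cumsum(counts * (0:255))
  w0 <- csum[1:255]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- msum[1:255] / w0
  mu1 <- (msum[256] - msum[1:255]) / w1
  sb <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  which.max(sb) # split s: classes {< s}, {>= s}; first max = smallest t
}

#' Detect weevil-sized blobs in a frame
#'
#' Binarizes the frame (dark-below-threshold by default, since weevils are
#' dark on the pale mango/background), labels 8-connected foreground
#' components, and keeps those whose pixel area lies inside the area window —
#' the "window filter" that rejects noise specks and the large mango region.
#'
#' Coordinates are 0-based with origin at the top-left, `(row, col)`;
#' bounding boxes are half-open `[top, bottom) x [left, right)`.
#'
#' @param frame Intensity matrix.
#' @param threshold Binarization threshold; defaults to [otsu_threshold()].
#' @param area_window `c(min, max)` acceptable component area in pixels.
#' @param polarity `"dark"` (foreground = intensity < threshold) or
#'   `"bright"`.
#' @param masks Also return each blob's binary mask as a list-column.
#' @return A tibble sorted by decreasing area: `blob`, `area`, `row`, `col`
#'   (centroid), `top`, `left`, `bottom`, `right`, and optionally `mask`.
#'   Empty (zero rows) when nothing passes the window.
#' @export
detect_blobs <- function(frame, threshold = NULL, area_window = c(1, Inf),
                         polarity = c("dark", "bright"), masks = FALSE) {
  polarity <- match.arg(polarity)
  if (is.null(threshold)) threshold <- otsu_threshold(frame)
  mask <- if (polarity == "dark") frame < threshold else frame >= threshold
  lab <- label_components_cpp(mask)
  k <- max(lab)
  empty <- tibble::tibble(blob = integer(), area = integer(),
                          row = numeric(), col = numeric(),
                          top = integer(), left = integer(),
                          bottom = integer(), right = integer())
  if (masks) empty$mask <- list()
  if (k == 0) return(empty)
  areas <- tabulate(lab, nbins = k)
  keep <- which(areas >= area_window[1] & areas <= area_window[2])
  if (length(keep) == 0) return(empty)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  rows <- purrr::map(keep, function(kk) {
    idx <- which(lab == kk)
    r <- (idx - 1L) %% nrow(frame) + 1L
    c <- (idx - 1L) %/% nrow(frame) + 1L
    out <- tibble::tibble(
      area = areas[kk],
      row = mean(r) - 1, col = mean(c) - 1,
      top = min(r) - 1L, left = min(c) - 1L,
      bottom = max(r), right = max(c)
    )
    if (masks) {
      m <- matrix(FALSE, nrow(frame), ncol(frame))
      m[idx] <- TRUE
      out$mask <- list(m)
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(blob = seq_len(nrow(out))), out)
  out
}

#' Bounding-box overlap and intersection-over-union
#'
#' Boxes are half-open `c(top, left, bottom, right)`: touching edges do not
#' overlap.
#'
#' @param a,b Numeric vectors `c(top, left, bottom, right)` with
#'   `bottom > top` and `right > left`.
#' @return A list with `overlap` (logical, intersection area > 0) and `iou`.
#' @examples
#' overlap_boxes(c(0, 0, 10, 10), c(5, 5, 15, 15)) # IoU 25/175
#' @export
overlap_boxes <- function(a, b) {
  check_box <- function(x) {
    assert_that(length(x) == 4 && all(is.finite(x)), "a box is c(top, left, bottom, right)")
    assert_that(x[3] > x[1] && x[4] > x[2], "degenerate (zero-area) box")
  }
  check_box(a); check_box(b)
  ih <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iw <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ih * iw
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  list(overlap = inter > 0, iou = inter / union)
}

#' Gate candidate detections by distance to track predictions
#'
#' A candidate farther than `max_jump` from every track prediction is
#' rejected as spurious (weevils cannot jump across the arena between
#' consecutive frames); remaining candidates are assigned to distinct tracks
#' minimizing total Euclidean distance (exhaustive over the small number of
#' tracks; ties go to the lower track id).
#'
#' @param predictions Matrix (tracks x 2) of predicted `(row, col)` positions.
#' @param candidates Matrix (candidates x 2) of detected centroids.
#' @param max_jump Maximum allowed displacement in pixels per frame.
#' @return Integer vector, one entry per candidate: the assigned track index,
#'   or `NA` for rejected candidates.
#' @export
gate_by_distance <- function(predictions, candidates, max_jump) {
  assert_that(max_jump > 0, "`max_jump` must be positive")
  predictions <- rbind(predictions)
  candidates <- rbind(candidates)
  m <- nrow(candidates); n <- nrow(predictions)
  if (m == 0) return(integer(0))
  d <- sqrt(outer(candidates[, 1], predictions[, 1], "-")^2 +
            outer(candidates[, 2], predictions[, 2], "-")^2)
  feasible <- d <= max_jump
  best <- rep(NA_integer_, m)
  best_score <- c(-1, Inf)
  assign_rec <- function(i, cur, used, n_assigned, total) {
    if (i > m) {
      if (n_assigned > best_score[1] ||
          (n_assigned == best_score[1] && total < best_score[2] - 1e-12)) {
        best <<- cur
        best_score <<- c(n_assigned, total)
      }
      return(invisible(NULL))
    }
    for (j in seq_len(n)) { # lower track ids first: ties resolve low
      if (!used[j] && feasible[i, j]) {
        cur[i] <- j
        used[j] <- TRUE
        assign_rec(i + 1, cur, used, n_assigned + 1, total + d[i, j])
        used[j] <- FALSE
        cur[i] <- NA_integer_
      }
    }
    assign_rec(i + 1, cur, used, n_assigned, total)
  }
  assign_rec(1, rep(NA_integer_, m), rep(FALSE, n), 0, 0)
  best
}

#' Create a constant-velocity Kalman track
#'
#' State is `(row, col, v_row, v_col)` in pixels and pixels/frame. The filter
#' carries each weevil across frames and coasts through missed detections.
#'
#' @param position Initial `(row, col)` position.
#' @param velocity Initial velocity, default zero.
#' @param process_noise,measurement_noise Noise standard deviations in pixels
#'   (process noise enters as `sigma_p^2 * I` per step).
#' @param p0 Initial state covariance scale (`p0 * I`).
#' @param id Track identifier.
#' @return An object of class `kalman_track`.
#' @seealso [kalman_step()]
#' @export
kalman_track <- function(position, velocity = c(0, 0),
                         process_noise = 1, measurement_noise = 1,
                         p0 = 10, id = 1L) {
  assert_that(length(position) == 2 && all(is.finite(position)),
              "`position` must be a finite (row, col) pair")
  structure(list(
    x = c(position, velocity),
    P = diag(p0, 4),
    sigma_p = process_noise, sigma_m = measurement_noise,
    misses = 0L, id = as.integer(id), last_box = NULL
  ), class = "kalman_track")
}

.kt_F <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 1))
.kt_H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))

kt_predict <- function(tr) {
  tr$x <- as.vector(.kt_F %*% tr$x)
  tr$P <- .kt_F %*% tr$P %*% t(.kt_F) + diag(tr$sigma_p^2, 4)
  tr
}

kt_update <- function(tr, z) {
  assert_that(length(z) == 2 && all(is.finite(z)), "measurement must be a finite (row, col) pair")
  S <- .kt_H %*% tr$P %*% t(.kt_H) + diag(tr$sigma_m^2, 2)
  K <- tr$P %*% t(.kt_H) %*% solve(S + diag(1e-12, 2))
  tr$x <- as.vector(tr$x + K %*% (z - .kt_H %*% tr$x))
  tr$P <- (diag(4) - K %*% .kt_H) %*% tr$P
  tr$misses <- 0L
  tr
}

#' Advance a Kalman track by one frame
#'
#' Performs the constant-velocity predict step (position advances by one
#' velocity increment) and, when a measurement is supplied, the standard
#' gain-weighted update of position and velocity. Without a measurement the
#' track coasts on its prediction and its miss counter increments.
#'
#' @param track A [kalman_track()].
#' @param z Optional `(row, col)` centroid measurement.
#' @return The updated track.
#' @export
kalman_step <- function(track, z = NULL) {
  assert_that(inherits(track, "kalman_track"), "`track` must be a kalman_track")
  track <- kt_predict(track)
  if (is.null(z)) {
    track$misses <- track$misses + 1L
  } else {
    track <- kt_update(track, z)
  }
  track
}

#' Video mating-segmentation parameters
#'
#' @param expected_area Expected single-weevil blob area in pixels; when
#'   `NULL` it is estimated as the median foreground-component area over the
#'   opening frames of the sequence.
#' @param area_window `c(min, max)` blob-area acceptance window; defaults to
#'   `[0.5, 3] * expected_area` so a merged mating pair stays in-window.
#' @param k_persist Number of consecutive frames the overlap (or separation)
#'   state must persist before an event starts (ends); suppresses flicker.
#' @param max_jump Distance gate in pixels/frame; defaults to five times the
#'   blob major-axis estimate `2 * sqrt(expected_area / pi)`.
#' @param process_noise,measurement_noise Kalman noise parameters (px).
#' @param polarity Foreground polarity for [detect_blobs()].
#' @return An object of class `videoseg_config`.
#' @export
videoseg_config <- function(expected_area = NULL, area_window = NULL,
                            k_persist = 3, max_jump = NULL,
                            process_noise = 1, measurement_noise = 1,
                            polarity = "dark") {
  assert_that(is_count(k_persist), "`k_persist` must be a positive integer")
  structure(list(expected_area = expected_area, area_window = area_window,
                 k_persist = as.integer(k_persist), max_jump = max_jump,
                 process_noise = process_noise,
                 measurement_noise = measurement_noise,
                 polarity = polarity),
            class = "videoseg_config")
}

# Fill in data-driven defaults from the opening frames.
resolve_videoseg_config <- function(config, frames) {
  if (is.null(config$expected_area)) {
    areas <- unlist(lapply(head(frames, 10), function(f) {
      b <- tryCatch(detect_blobs(f), error = function(e) NULL)
      if (is.null(b)) numeric(0) else b$area
    }))
    assert_that(length(areas) > 0, "could not estimate blob area from opening frames")
    config$expected_area <- median(areas)
  }
  if (is.null(config$area_window)) {
    config$area_window <- config$expected_area * c(0.5, 3)
  }
  if (is.null(config$max_jump)) {
    config$max_jump <- 5 * 2 * sqrt(config$expected_area / pi)
  }
  config
}

#' Segment mating events from a frame sequence
#'
#' The full video pipeline: per frame, Otsu thresholding, area-filtered blob
#' detection, distance gating against the two weevil tracks' Kalman
#' predictions, and track update. A frame is flagged as overlapping when the
#' two tracks' current bounding boxes intersect, or when a single in-window
#' blob remains where two tracks are active (the mounted pair merges into one
#' component; both tracks then associate to the merged blob). A mating event
#' starts at the first frame of a run of at least `k_persist` consecutive
#' overlap flags and ends at the first frame of a run of at least `k_persist`
#' non-overlap flags; timestamps are `frame_index / fps` (0-based frames).
#'
#' @param frames List of grayscale frame matrices, a `video_scene`, or a
#'   frame directory readable by [read_frames()].
#' @param fps Frames per second (taken from the scene/sidecar if available).
#' @param config A [videoseg_config()].
#' @return A tibble of class `mating_events` with columns `event`, `start_s`,
#'   `end_s`, `duration_s`, and attributes `debug` (per-frame blob count,
#'   track count and overlap flag) and `fps`. Zero rows when no event (or
#'   fewer than two weevils) is observed.
#' @export
segment_mating <- function(frames, fps = NULL, config = videoseg_config()) {
  if (inherits(frames, "video_scene")) {
    fps <- frames$scenario$fps
    frames <- frames$frames
  } else if (is.character(frames)) {
    fd <- read_frames(frames)
    if (is.null(fps)) fps <- fd$fps
    frames <- fd$frames
  }
  assert_that(!is.null(fps) && fps > 0, "`fps` must be supplied and positive")
  assert_that(length(frames) >= 1, "no frames to process")
  config <- resolve_videoseg_config(config, frames)
  n <- length(frames)
  tracks <- list()
  flags <- logical(n)
  n_blobs <- integer(n)
  n_tracks <- integer(n)
  ever_two <- FALSE
  for (i in seq_len(n)) {
    blobs <- tryCatch(
      detect_blobs(frames[[i]], area_window = config$area_window,
                   polarity = config$polarity),
      error = function(e) NULL)
    nb <- if (is.null(blobs)) 0L else nrow(blobs)
    n_blobs[i] <- nb
    merged <- FALSE
    assigned_boxes <- list()
    if (length(tracks)) tracks <- lapply(tracks, kt_predict)
    if (nb > 0 && length(tracks) > 0) {
      preds <- do.call(rbind, lapply(tracks, function(t) t$x[1:2]))
      cand <- cbind(blobs$row, blobs$col)
      if (length(tracks) == 2 && nb == 1) {
        d <- sqrt(colSums((t(preds) - c(cand))^2))
        if (all(d <= config$max_jump)) {
          # merged pair: both tracks associate to the single blob
          box <- c(blobs$top[1], blobs$left[1], blobs$bottom[1], blobs$right[1])
          tracks <- lapply(tracks, function(t) {
            t <- kt_update(t, c(cand))
            t$last_box <- box
            t
          })
          merged <- TRUE
        }
      }
      if (!merged) {
        assign <- gate_by_distance(preds, cand, config$max_jump)
        updated <- logical(length(tracks))
        for (ci in seq_len(nb)) {
          j <- assign[ci]
          if (!is.na(j)) {
            tracks[[j]] <- kt_update(tracks[[j]],
                                     c(blobs$row[ci], blobs$col[ci]))
            tracks[[j]]$last_box <- c(blobs$top[ci], blobs$left[ci],
                                      blobs$bottom[ci], blobs$right[ci])
            updated[j] <- TRUE
            assigned_boxes[[j]] <- tracks[[j]]$last_box
          }
        }
        for (j in which(!updated)) tracks[[j]]$misses <- tracks[[j]]$misses + 1L
        # spawn tracks for unassigned blobs while fewer than two are active
        for (ci in which(is.na(assign))) {
          if (length(tracks) >= 2) break
          tr <- kalman_track(c(blobs$row[ci], blobs$col[ci]),
                             process_noise = config$process_noise,
                             measurement_noise = config$measurement_noise,
                             id = length(tracks) + 1L)
          tr$last_box <- c(blobs$top[ci], blobs$left[ci], blobs$bottom[ci], blobs$right[ci])
          tracks <- c(tracks, list(tr))
        }
      }
    } else if (nb > 0) {
      for (ci in seq_len(min(nb, 2L))) {
        tr <- kalman_track(c(blobs$row[ci], blobs$col[ci]),
                           process_noise = config$process_noise,
                           measurement_noise = config$measurement_noise,
                           id = length(tracks) + 1L)
        tr$last_box <- c(blobs$top[ci], blobs$left[ci], blobs$bottom[ci], blobs$right[ci])
        tracks <- c(tracks, list(tr))
      }
    } else if (length(tracks)) {
      tracks <- lapply(tracks, function(t) { t$misses <- t$misses + 1L; t })
    }
    n_tracks[i] <- length(tracks)
    if (length(tracks) == 2) ever_two <- TRUE
    flag <- FALSE
    if (length(tracks) == 2) {
      if (merged) {
        flag <- TRUE
      } else if (nb >= 2 && tracks[[1]]$misses == 0 && tracks[[2]]$misses == 0 &&
                 !is.null(tracks[[1]]$last_box) && !is.null(tracks[[2]]$last_box)) {
        flag <- overlap_boxes(tracks[[1]]$last_box, tracks[[2]]$last_box)$overlap
      }
    }
    flags[i] <- flag
  }
  debug <- tibble::tibble(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / fps,
                          n_blobs = n_blobs, n_tracks = n_tracks, overlap = flags)
  if (!ever_two) {
    warning("fewer than two weevils were ever detected; returning no events")
    ev <- tibble::tibble(event = integer(), start_s = numeric(),
                         end_s = numeric(), duration_s = numeric())
  } else {
    ev <- events_from_flags(flags, fps, config$k_persist)
  }
  structure(ev, class = c("mating_events", class(ev)),
            debug = debug, fps = fps, config = config)
}

# State machine over the per-frame overlap flags: runs shorter than
# k_persist do not change state, so flicker neither starts nor ends events.
events_from_flags <- function(flags, fps, k_persist) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  in_event <- FALSE
  ev_start <- NA_integer_
  out <- list()
  for (i in seq_along(r$lengths)) {
    if (!in_event && r$values[i] && r$lengths[i] >= k_persist) {
      in_event <- TRUE
      ev_start <- starts[i]
    } else if (in_event && !r$values[i] && r$lengths[i] >= k_persist) {
      out[[length(out) + 1]] <- c(ev_start, starts[i])
      in_event <- FALSE
    }
  }
  if (in_event) out[[length(out) + 1]] <- c(ev_start, length(flags) + 1L)
  if (length(out) == 0) {
    return(tibble::tibble(event = integer(), start_s = numeric(),
                          end_s = numeric(), duration_s = numeric()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(
    event = seq_len(nrow(m)),
    start_s = (m[, 1] - 1) / fps,
    end_s = (m[, 2] - 1) / fps,
    duration_s = (m[, 2] - m[, 1]) / fps
  )
}
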