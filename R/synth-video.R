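#' Scripted two-weevil video scenario
#'
#' Describes a synthetic grayscale sequence emulating chamber footage of a
#' weevil pair: two dark elliptical blobs on a light background (with an
#' optional static dark mango region) executing a chase, then mounting
#' (rendered as the two blobs merging into a single overlapping pair), then
#' separating. The overlap phase is the ground-truth mating event.
#'
#' The phase script is built from the durations: chase frames, then
#' `round(mating_s * fps)` overlap frames, then separation frames. When
#' `mating_s` is `NULL` it is drawn uniformly from `mating_range` under the
#' scenario seed — by default 15--20 s at 10 fps, a desk-scale stand-in for
#' the 15--20 min a weevil pair stays mounted. `mating_s = 0` yields an
#' event-free chase-only video. A custom `script` (tibble with `phase`,
#' `start_frame`, `end_frame`, half-open 0-based frame ranges) may be passed
#' instead; phases must be contiguous, non-overlapping and ordered.
#'
#' @param frame_size `c(height, width)` in pixels.
#' @param fps Frames per second.
#' @param chase_s,separate_s Durations (s) of the chase and separation phases.
#' @param mating_s Overlap-phase duration in seconds, `0` for none, or `NULL`
#'   to draw from `mating_range`.
#' @param mating_range Length-2 range (s) from which `mating_s` is drawn.
#' @param blob_axes `c(semi_major, semi_minor)` ellipse semi-axes in pixels
#'   (major axis along columns).
#' @param mango Render a static dark disc (the mango) in the upper right.
#' @param noise_sd Standard deviation of additive pixel noise (gray levels).
#' @param seed Integer RNG seed.
#' @return An object of class `video_scenario`.
#' @param script Optional explicit phase table overriding the durations.
#' @examples
#' video_scenario(mating_s = 10, seed = 2)
#' @export
video_scenario <- function(frame_size = c(120, 160), fps = 10,
                           chase_s = 5, mating_s = NULL, separate_s = 5,
                           mating_range = c(15, 20),
                           blob_axes = c(9, 6), mango = TRUE,
                           noise_sd = 2, seed = 1L, script = NULL) {
  assert_that(length(frame_size) == 2 && all(frame_size >= 40),
              "`frame_size` must be c(height, width), each at least 40 px")
  assert_that(fps > 0, "`fps` must be positive")
  assert_that(length(blob_axes) == 2 && all(blob_axes >= 2) && blob_axes[1] >= blob_axes[2],
              "`blob_axes` must be c(semi_major, semi_minor) with major >= minor >= 2")
  seed <- as.integer(seed)
  if (is.null(script)) {
    if (is.null(mating_s)) {
      assert_that(length(mating_range) == 2 && mating_range[1] <= mating_range[2],
                  "`mating_range` must be an increasing length-2 range")
      mating_s <- with_seed(seed, runif(1, mating_range[1], mating_range[2]))
    }
    assert_that(chase_s > 0 && separate_s >= 0 && mating_s >= 0,
                "phase durations must be non-negative (chase positive)")
    nf <- c(chase = round(chase_s * fps), overlap = round(mating_s * fps),
            separate = round(separate_s * fps))
    ends <- cumsum(nf)
    script <- tibble::tibble(
      phase = names(nf), start_frame = unname(ends - nf), end_frame = unname(ends)
    )
    script <- script[script$end_frame > script$start_frame, ]
  }
  validate_script(script)
  n_frames <- max(script$end_frame)
  structure(list(frame_size = as.integer(frame_size), fps = fps,
                 n_frames = as.integer(n_frames), script = script,
                 blob_axes = blob_axes, mango = isTRUE(mango),
                 noise_sd = noise_sd, seed = seed),
            class = "video_scenario")
}

validate_script <- function(script) {
  assert_that(is.data.frame(script) &&
                all(c("phase", "start_frame", "end_frame") %in% names(script)),
              "`script` must have columns phase, start_frame, end_frame")
  assert_that(all(script$phase %in% c("chase", "overlap", "separate")),
              "script phases must be chase, overlap or separate")
  assert_that(all(script$end_frame > script$start_frame),
              "script phases must be non-empty (end_frame > start_frame)")
  if (nrow(script) > 1) {
    assert_that(all(script$start_frame[-1] == script$end_frame[-nrow(script)]),
                "script phases must be contiguous, non-overlapping and ordered")
  }
  assert_that(script$start_frame[1] == 0, "script must start at frame 0")
  ord <- match(script$phase, c("chase", "overlap", "separate"))
  assert_that(!is.unsorted(ord), "script phases are out of order")
  invisible(script)
}

#' @export
print.video_scenario <- function(x, ...) {
  cat(sprintf("<video_scenario> %dx%d px, %g fps, %d frames | phases: %s | seed %d\n",
              x$frame_size[1], x$frame_size[2], x$fps, x$n_frames,
              paste(sprintf("%s[%d,%d)", x$script$phase, x$script$start_frame,
                            x$script$end_frame), collapse = " "), x$seed))
  invisible(x)
}

# Gray levels of the rendered scene.
.gray <- c(background = 220, blob = 40, mango = 90)

# Inter-blob gap (px, center to center along the approach axis) per frame.
# Far apart (40 px) while chasing, closing at 9 px/frame over the last
# frames before overlap so that bounding boxes (major axis 2a) intersect at
# most one frame before the scripted overlap; mirrored on separation.
gap_schedule <- function(frame, script, gap_touch = 6, gap_far = 40, rate = 9) {
  ov <- script[script$phase == "overlap", ]
  if (nrow(ov) == 0) return(gap_far)
  if (frame >= ov$start_frame && frame < ov$end_frame) return(gap_touch)
  if (frame < ov$start_frame) {
    d <- ov$start_frame - frame
  } else {
    d <- frame - ov$end_frame + 1
  }
  min(gap_far, gap_touch + rate * d)
}

# Continuous blob center positions (1-based row/col) for every frame.
blob_positions <- function(scenario) {
  h <- scenario$frame_size[1]; w <- scenario$frame_size[2]
  a <- scenario$blob_axes[1]; b <- scenario$blob_axes[2]
  frames <- seq_len(scenario$n_frames) - 1
  # female wanders slowly around a point in the lower-left quadrant
  r0 <- 0.70 * h; c0 <- 0.40 * w
  rf <- r0 + 4 * sin(0.06 * frames)
  cf <- c0 + 5 * sin(0.041 * frames + 1)
  gap <- vapply(frames, gap_schedule, numeric(1), script = scenario$script)
  rm_ <- rf
  cm_ <- cf - gap
  pos <- tibble::tibble(
    frame = rep(frames, 2),
    blob = rep(c("female", "male"), each = length(frames)),
    row = c(rf, rm_), col = c(cf, cm_)
  )
  assert_that(all(pos$row - b >= 1) && all(pos$row + b <= h) &&
                all(pos$col - a >= 1) && all(pos$col + a <= w),
              "a blob leaves the frame under this scenario; enlarge frame_size")
  pos
}

render_ellipse <- function(frame_mat, r0, c0, a, b, value) {
  rr <- max(1, floor(r0 - b)):min(nrow(frame_mat), ceiling(r0 + b))
  cc <- max(1, floor(c0 - a)):min(ncol(frame_mat), ceiling(c0 + a))
  d <- outer(((rr - r0) / b)^2, ((cc - c0) / a)^2, "+")
  patch <- frame_mat[rr, cc]
  patch[d <= 1] <- value
  frame_mat[rr, cc] <- patch
  frame_mat
}

#' Generate a scripted two-weevil video with ground truth
#'
#' Renders 8-bit grayscale frames per the scenario script (see
#' [video_scenario()]): background gray 220, weevil blobs gray 40, optional
#' mango disc gray 90, plus Gaussian pixel noise. During the overlap phase
#' the two ellipses are drawn 6 px apart so they form a single connected
#' foreground component (the mounted pair). Deterministic under the scenario
#' seed.
#'
#' @param scenario A [video_scenario()].
#' @return An object of class `video_scene`: list with `frames` (list of
#'   integer matrices in `[0, 255]`), `ground_truth` (tibble
#'   `event_start_s`, `event_end_s` of scripted mating intervals), `positions`
#'   (per-frame blob centers), and `scenario`.
#' @export
generate_video <- function(scenario) {
  assert_that(inherits(scenario, "video_scenario"), "`scenario` must be a video_scenario")
  h <- scenario$frame_size[1]; w <- scenario$frame_size[2]
  a <- scenario$blob_axes[1]; b <- scenario$blob_axes[2]
  pos <- blob_positions(scenario)
  base <- matrix(.gray["background"], h, w)
  if (scenario$mango) {
    mr <- 0.22 * h; mc <- w - 0.20 * w; rad <- 0.18 * min(h, w)
    base <- render_ellipse(base, mr, mc, rad, rad, .gray["mango"])
  }
  frames <- with_seed(scenario$seed + 1L, lapply(seq_len(scenario$n_frames), function(i) {
    f <- base
    p <- pos[pos$frame == i - 1, ]
    for (k in seq_len(nrow(p))) {
      f <- render_ellipse(f, p$row[k], p$col[k], a, b, .gray["blob"])
    }
    if (scenario$noise_sd > 0) {
      f <- f + matrix(rnorm(h * w, sd = scenario$noise_sd), h, w)
    }
    matrix(as.integer(pmin(pmax(round(f), 0), 255)), h, w)
  }))
  ov <- scenario$script[scenario$script$phase == "overlap", ]
  gt <- tibble::tibble(event_start_s = ov$start_frame / scenario$fps,
                       event_end_s = ov$end_frame / scenario$fps)
  structure(list(frames = frames, ground_truth = gt, positions = pos,
                 scenario = scenario),
            class = "video_scene")
}

#' @export
print.video_scene <- function(x, ...) {
  cat(sprintf("<video_scene> %d frames %dx%d at %g fps | %d ground-truth mating event(s)\n",
              length(x$frames), x$scenario$frame_size[1], x$scenario$frame_size[2],
              x$scenario$fps, nrow(x$ground_truth)))
  invisible(x)
}

#' Write video frames to a directory
#'
#' Frames are written as zero-padded numbered images plus a JSON sidecar
#' (`meta.json`) with `fps`, `frame_count`, `height`, `width`. PGM files are
#' plain-text (P2); PNG uses 8-bit grayscale.
#'
#' @param scene A `video_scene` (or plain list of integer matrices, in which
#'   case `fps` must be given).
#' @param dir Output directory (created if missing).
#' @param format `"pgm"` or `"png"`.
#' @param fps Frames per second for the sidecar (taken from the scene when
#'   available).
#' @return Invisibly, the directory.
#' @export
write_frames <- function(scene, dir, format = c("pgm", "png"), fps = NULL) {
  format <- match.arg(format)
  if (inherits(scene, "video_scene")) {
    frames <- scene$frames
    fps <- scene$scenario$fps
  } else {
    frames <- scene
    assert_that(!is.null(fps), "`fps` is required when writing a bare frame list")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    path <- file.path(dir, sprintf("frame_%06d.%s", i - 1, format))
    if (format == "pgm") {
      con <- file(path, "w")
      writeLines(c("P2", sprintf("%d %d", ncol(f), nrow(f)), "255"), con)
      write(t(f), file = con, ncolumns = ncol(f))
      close(con)
    } else {
      png::writePNG(f / 255, path)
    }
    paths[i] <- path
  }
  jsonlite::write_json(
    list(fps = fps, frame_count = length(frames),
         height = nrow(frames[[1]]), width = ncol(frames[[1]])),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame directory written by [write_frames()]
#'
#' @param dir Directory containing numbered `.pgm`/`.png` frames and
#'   `meta.json`.
#' @return A list with `frames` (list of integer matrices) and `fps`.
#' @export
read_frames <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  assert_that(file.exists(meta_path), "missing meta.json sidecar (need fps metadata)")
  meta <- jsonlite::read_json(meta_path)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.(pgm|png)$", full.names = TRUE))
  assert_that(length(files) > 0, "no frame files found")
  frames <- lapply(files, function(p) {
    if (grepl("\\.png$", p)) {
      matrix(as.integer(round(png::readPNG(p) * 255)), nrow = meta$height)
    } else {
      ln <- readLines(p)
      assert_that(ln[1] == "P2", "only plain (P2) PGM is supported")
      vals <- scan(text = paste(ln[-(1:3)], collapse = " "), quiet = TRUE)
      matrix(as.integer(vals), nrow = meta$height, byrow = TRUE)
    }
  })
  list(frames = frames, fps = meta$fps)
}
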