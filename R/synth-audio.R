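#' Synthetic acoustic scenario description
#'
#' Parameters of a labeled synthetic audio scene standing in for chamber
#' recordings of weevil activity: equal numbers of fixed-length segments per
#' activity class, each non-resting segment carrying band-limited impulsive
#' bursts inside its class band, embedded in white Gaussian noise at a
#' configurable signal-to-noise ratio.
#'
#' @param sample_rate Sampling rate in Hz (default 44.1 kHz, comfortably
#'   representing the 4--5 kHz adult-walking band).
#' @param segment_length Segment length in seconds (default 5 s).
#' @param segments_per_class Number of segments generated for each class.
#' @param snr_db Segment-wide signal-to-noise ratio in dB,
#'   `10*log10(signal power / noise power)`; `Inf` disables noise on
#'   sound-producing classes.
#' @param burst_rate Mean burst rate (events per second) of the Poisson burst
#'   process.
#' @param seed Integer RNG seed; fixes the scene exactly.
#' @return An object of class `audio_scenario`.
#' @examples
#' audio_scenario(segments_per_class = 2, snr_db = 30, seed = 7)
#' @export
audio_scenario <- function(sample_rate = 44100, segment_length = 5,
                           segments_per_class = 10, snr_db = 30,
                           burst_rate = 10, seed = 1L) {
  assert_that(sample_rate > 0, "`sample_rate` must be positive")
  assert_that(length(segment_length) == 1 && segment_length > 0,
              "`segment_length` must be positive")
  assert_that(is_count(segments_per_class), "`segments_per_class` must be a positive integer")
  assert_that(length(snr_db) == 1 && (is.infinite(snr_db) || is.finite(snr_db)),
              "`snr_db` must be a single number (possibly Inf)")
  assert_that(burst_rate > 0, "`burst_rate` must be positive")
  structure(list(sample_rate = sample_rate, segment_length = segment_length,
                 segments_per_class = as.integer(segments_per_class),
                 snr_db = snr_db, burst_rate = burst_rate,
                 seed = as.integer(seed)),
            class = "audio_scenario")
}

#' @export
print.audio_scenario <- function(x, ...) {
  cat(sprintf("<audio_scenario> %g Hz | %g s segments x %d per class | SNR %g dB | burst rate %g/s | seed %d\n",
              x$sample_rate, x$segment_length, x$segments_per_class,
              x$snr_db, x$burst_rate, x$seed))
  invisible(x)
}

# Reference RMS of the burst-train component; leaves 16-bit headroom for
# burst peaks (crest factors of impulsive trains run 15-25 dB).
.sig_rms <- 0.05

# Noise RMS implied by an SNR; resting (noise-only) segments fall back to the
# 60 dB-equivalent level when snr_db = Inf so they are never all-zero.
noise_rms_for <- function(snr_db, resting = FALSE) {
  if (is.infinite(snr_db)) {
    if (resting) .sig_rms / 10^(60 / 20) else 0
  } else {
    .sig_rms / 10^(snr_db / 20)
  }
}

# One synthetic segment for one activity class. Caller owns the RNG state.
synth_activity_segment <- function(label, scenario, bands) {
  n <- round(scenario$segment_length * scenario$sample_rate)
  sr <- scenario$sample_rate
  if (label == "resting") {
    return(rnorm(n, sd = noise_rms_for(scenario$snr_db, resting = TRUE)))
  }
  band <- bands[bands$activity == label, ]
  assert_that(nrow(band) == 1, sprintf("no band defined for class '%s'", label))
  n_bursts <- max(1L, rpois(1, scenario$burst_rate * scenario$segment_length))
  onsets <- sort(runif(n_bursts, 0, scenario$segment_length))
  durs <- runif(n_bursts, 0.005, 0.020)
  x <- numeric(n)
  for (b in seq_len(n_bursts)) {
    i0 <- floor(onsets[b] * sr) + 1
    i1 <- min(n, i0 + round(durs[b] * sr) - 1)
    x[i0:i1] <- x[i0:i1] + rnorm(i1 - i0 + 1)
  }
  bf <- signal::butter(4, c(band$f_lo, band$f_hi) / (sr / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  x <- x / rms(x) * .sig_rms
  nr <- noise_rms_for(scenario$snr_db)
  if (nr > 0) x <- x + rnorm(n, sd = nr)
  x
}

#' Generate a labeled synthetic audio scene
#'
#' Draws `segments_per_class` segments for each requested class, in class
#' order. Sound-producing classes (mating, pupal movement, adult walking) are
#' Poisson-timed 5--20 ms white-noise bursts band-passed into the class band
#' (order-4 zero-phase Butterworth) and amplitude-normalized per segment,
#' with additive white Gaussian noise at `snr_db`; `resting` segments are
#' noise only. Deterministic under the scenario seed.
#'
#' @param scenario An [audio_scenario()].
#' @param bands Band table from [band_scheme()]; all edges must lie below
#'   Nyquist.
#' @param classes Classes to generate, a subset of [activity_levels()].
#' @param dir Optional output directory: writes `scene.wav` (all segments
#'   concatenated, 16-bit PCM mono) and `labels.csv`
#'   (`segment_index,start_s,end_s,label`).
#' @return An object of class `audio_scene`: list with `segments` (tibble
#'   with `segment`, `label`, `sample_rate`, `samples` list-column), `labels`
#'   (the ground-truth label table), `scenario`, and `bands`.
#' @examples
#' sc <- audio_scenario(sample_rate = 16000, segment_length = 1,
#'                      segments_per_class = 2, seed = 3)
#' scene <- generate_audio(sc, band_scheme(adult_walking = c(4000, 5000)))
#' scene$labels
#' @export
generate_audio <- function(scenario, bands = band_scheme(),
                           classes = activity_levels(), dir = NULL) {
  assert_that(inherits(scenario, "audio_scenario"), "`scenario` must be an audio_scenario")
  assert_that(all(classes %in% activity_levels()),
              "`classes` must be a subset of activity_levels()")
  validate_bands(bands, scenario$sample_rate)
  labs <- rep(classes, each = scenario$segments_per_class)
  segs <- with_seed(scenario$seed,
    lapply(labs, synth_activity_segment, scenario = scenario, bands = bands))
  n_seg <- length(labs)
  seg_len <- scenario$segment_length
  segments <- tibble::tibble(
    segment = seq_len(n_seg),
    label = labs,
    sample_rate = scenario$sample_rate,
    samples = segs
  )
  labels <- tibble::tibble(
    segment_index = seq_len(n_seg),
    start_s = (seq_len(n_seg) - 1) * seg_len,
    end_s = seq_len(n_seg) * seg_len,
    label = labs
  )
  scene <- structure(list(segments = segments, labels = labels,
                          scenario = scenario, bands = bands),
                     class = "audio_scene")
  if (!is.null(dir)) write_audio_scene(scene, dir)
  scene
}

#' Write an audio scene to disk
#'
#' @param scene An `audio_scene` from [generate_audio()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_audio_scene <- function(scene, dir) {
  assert_that(inherits(scene, "audio_scene"), "`scene` must be an audio_scene")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wav <- file.path(dir, "scene.wav")
  csv <- file.path(dir, "labels.csv")
  write_wav(unlist(scene$segments$samples), scene$scenario$sample_rate, wav)
  utils::write.csv(scene$labels, csv, row.names = FALSE, quote = FALSE)
  write_manifest(dir, c(wav, csv), extra = unclass(scene$scenario))
  invisible(c(wav = wav, labels = csv))
}

#' @export
print.audio_scene <- function(x, ...) {
  cat(sprintf("<audio_scene> %d segments (%s), %g s at %g Hz\n",
              nrow(x$segments),
              paste(unique(x$segments$label), collapse = ", "),
              x$scenario$segment_length, x$scenario$sample_rate))
  invisible(x)
}
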