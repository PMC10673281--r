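#' Run the full acoustic classification pipeline
#'
#' Synthesis (or ingestion), RMS normalization, MFCC aggregate features,
#' per-task stratified 70/30 split, SVM training and evaluation: the complete
#' audio path from raw segments to confusion-matrix reports. Segments are
#' generated and featurized one at a time, so memory stays flat in the number
#' of segments.
#'
#' Three binary tasks mirror the study design — `pupal` (pupa moving vs
#' resting), `adult` (adult walking vs resting), `mating` (mating vs
#' everything else) — plus an optional 4-class task `all`. For each task a
#' `testing` report comes from the 70/30 split at the run seed and a
#' `validation` report from an identical split/train/evaluate pass at a
#' second seed.
#'
#' @param scenario An [audio_scenario()]; its seed drives all randomness.
#' @param bands Band table from [band_scheme()].
#' @param cfg An [mfcc_config()]; defaults to the standard front-end at the
#'   scenario's sampling rate.
#' @param tasks Subset of `c("pupal", "adult", "mating", "all")`.
#' @param train_frac Training fraction for every split.
#' @param validation Also compute the second-seed validation reports.
#' @param band_rule Also score the dominant-band rule baseline per task.
#' @param segments Optional pre-built segment table (columns `segment`,
#'   `label`, `sample_rate`, `samples`) to use instead of synthesis, e.g.
#'   from [segment_waveform()] on a real recording.
#' @param out_dir Optional directory: writes `features.csv`, `reports.csv`
#'   and a checksummed manifest.
#' @return An object of class `audio_run`: list with `features` (per-segment
#'   feature/band table), `reports` (tibble: task, phase, accuracy, error, n,
#'   confusion list-column), `report_objects`, `models`, `overall`
#'   (both overall-accuracy variants over the testing reports), `band_rule`,
#'   and the inputs.
#' @examples
#' \donttest{
#' run <- run_audio_pipeline(audio_scenario(sample_rate = 16000,
#'   segment_length = 1, segments_per_class = 10, snr_db = 30, seed = 7),
#'   bands = band_scheme(adult_walking = c(4000, 5000)))
#' run$reports
#' }
#' @export
run_audio_pipeline <- function(scenario = audio_scenario(),
                               bands = band_scheme(),
                               cfg = NULL,
                               tasks = c("pupal", "adult", "mating"),
                               train_frac = 0.7,
                               validation = TRUE,
                               band_rule = TRUE,
                               segments = NULL,
                               out_dir = NULL) {
  assert_that(all(tasks %in% c("pupal", "adult", "mating", "all")),
              "tasks must be among pupal, adult, mating, all")
  if (is.null(cfg)) cfg <- mfcc_config(scenario$sample_rate)
  fb <- mel_filterbank(cfg)
  D <- dct2_matrix(cfg$n_coefficients, cfg$n_mel_filters)
  featurize <- function(x, sr) {
    x <- rms_normalize.numeric(x)
    C <- mel_log_energies(x, cfg, fb) %*% t(D)
    if (!band_rule) return(stats_row(C))
    dplyr::bind_cols(stats_row(C), dominant_band.numeric(x, sr, bands))
  }
  if (is.null(segments)) {
    validate_bands(bands, scenario$sample_rate)
    labs <- rep(activity_levels(), each = scenario$segments_per_class)
    features <- with_seed(scenario$seed, {
      rows <- lapply(labs, function(lb) {
        x <- synth_activity_segment(lb, scenario, bands)
        featurize(x, scenario$sample_rate)
      })
      dplyr::bind_rows(rows)
    })
    features <- dplyr::bind_cols(
      tibble::tibble(segment = seq_along(labs), label = labs), features)
  } else {
    assert_that(all(c("label", "samples", "sample_rate") %in% names(segments)),
                "`segments` must have label, sample_rate and samples columns")
    features <- dplyr::bind_cols(
      tibble::tibble(segment = seq_len(nrow(segments)), label = segments$label),
      dplyr::bind_rows(purrr::map2(segments$samples, segments$sample_rate, featurize)))
  }
  feat_cols <- grep("^c\\d+_(mean|sd)$", names(features), value = TRUE)

  task_view <- function(task) {
    switch(task,
      pupal = dplyr::filter(features, .data$label %in% c("pupa_moving", "resting")),
      adult = dplyr::filter(features, .data$label %in% c("adult_walking", "resting")),
      mating = dplyr::mutate(features,
        label = ifelse(.data$label == "mating", "mating", "non_mating")),
      all = features
    )
  }
  map_rule <- function(task, rule_pred) {
    switch(task,
      mating = ifelse(rule_pred == "mating", "mating", "non_mating"),
      rule_pred
    )
  }

  reports <- list(); models <- list(); band_rows <- list()
  for (ti in seq_along(tasks)) {
    task <- tasks[ti]
    dat <- task_view(task)
    run_once <- function(seed, phase) {
      sp <- split_dataset(dat, train_frac = train_frac, stratify = TRUE, seed = seed)
      model <- train_activity_svm(sp$train, feature_cols = feat_cols)
      list(report = evaluate(model, sp$test, phase), model = model, split = sp)
    }
    test_run <- run_once(scenario$seed + ti, "testing")
    reports[[paste0(task, ".testing")]] <- test_run$report
    models[[task]] <- test_run$model
    if (validation) {
      val_run <- run_once(scenario$seed + ti + 104729L, "validation")
      reports[[paste0(task, ".validation")]] <- val_run$report
    }
    if (band_rule) {
      test_set <- test_run$split$test
      rule <- map_rule(task, band_rule_predict(test_set))
      band_rows[[task]] <- tibble::tibble(
        task = task, accuracy = 100 * mean(rule == test_set$label),
        n = nrow(test_set))
    }
  }
  report_tbl <- dplyr::bind_rows(lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    tibble::tibble(task = sub("\\..*$", "", nm), phase = r$phase,
                   accuracy = r$accuracy, error = r$error, n = r$n,
                   confusion = list(r$confusion))
  }))
  testing_reports <- reports[grepl("\\.testing$", names(reports))]
  out <- structure(list(
    features = features,
    reports = report_tbl,
    report_objects = reports,
    models = models,
    overall = overall_accuracy(unname(testing_reports)),
    band_rule = dplyr::bind_rows(band_rows),
    scenario = scenario, bands = bands, cfg = cfg
  ), class = "audio_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fpath <- file.path(out_dir, "features.csv")
    rpath <- file.path(out_dir, "reports.csv")
    utils::write.csv(features, fpath, row.names = FALSE)
    utils::write.csv(dplyr::select(report_tbl, -"confusion"), rpath, row.names = FALSE)
    write_manifest(out_dir, c(fpath, rpath), extra = unclass(scenario))
  }
  out
}

#' @export
print.audio_run <- function(x, ...) {
  cat(sprintf("<audio_run> %d segments | tasks: %s\n", nrow(x$features),
              paste(unique(x$reports$task), collapse = ", ")))
  print(dplyr::select(x$reports, -"confusion"))
  cat("overall (testing):\n")
  print(x$overall)
  invisible(x)
}

#' @method tidy audio_run
#' @export
tidy.audio_run <- function(x, ...) dplyr::select(x$reports, -"confusion")

#' @method glance audio_run
#' @export
glance.audio_run <- function(x, ...) {
  testing <- dplyr::filter(x$reports, .data$phase == "testing")
  wide <- stats::setNames(as.list(testing$accuracy),
                          paste0(testing$task, "_accuracy"))
  tibble::as_tibble(c(
    list(n_segments = nrow(x$features), snr_db = x$scenario$snr_db),
    wide,
    list(overall_pooled = x$overall$accuracy[x$overall$method == "pooled"],
         overall_unweighted = x$overall$accuracy[x$overall$method == "unweighted_mean"])
  ))
}

#' Run the video mating-segmentation pipeline
#'
#' Generates (or ingests) scripted weevil videos, runs [segment_mating()],
#' and scores the recovered events against ground truth when available.
#'
#' @param scenarios A [video_scenario()], a list of them, or a list of
#'   `video_scene` objects.
#' @param config A [videoseg_config()].
#' @param out_dir Optional directory: per-video `events_<k>.csv`
#'   (`event_id,start_s,end_s,duration_s`), per-frame debug CSVs and a
#'   manifest.
#' @return An object of class `video_run`: tibble with one row per video
#'   (`video`, `n_truth`, `n_recovered`, `gt_start_s`, `gt_duration_s`,
#'   `start_s`, `duration_s`, `start_error_s`, `duration_error_s`) and the
#'   recovered event tables in attribute `events`.
#' @export
run_video_pipeline <- function(scenarios, config = videoseg_config(),
                               out_dir = NULL) {
  if (inherits(scenarios, "video_scenario") || inherits(scenarios, "video_scene")) {
    scenarios <- list(scenarios)
  }
  all_events <- list()
  rows <- list()
  files <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(scenarios)) {
    scene <- scenarios[[k]]
    if (inherits(scene, "video_scenario")) scene <- generate_video(scene)
    assert_that(inherits(scene, "video_scene"), "scenarios must be video_scenario or video_scene objects")
    ev <- segment_mating(scene, config = config)
    all_events[[k]] <- ev
    gt <- scene$ground_truth
    rows[[k]] <- tibble::tibble(
      video = k,
      n_truth = nrow(gt),
      n_recovered = nrow(ev),
      gt_start_s = if (nrow(gt)) gt$event_start_s[1] else NA_real_,
      gt_duration_s = if (nrow(gt)) gt$event_end_s[1] - gt$event_start_s[1] else NA_real_,
      start_s = if (nrow(ev)) ev$start_s[1] else NA_real_,
      duration_s = if (nrow(ev)) ev$duration_s[1] else NA_real_
    )
    if (!is.null(out_dir)) {
      epath <- file.path(out_dir, sprintf("events_%03d.csv", k))
      edf <- data.frame(event_id = ev$event, start_s = ev$start_s,
                        end_s = ev$end_s, duration_s = ev$duration_s)
      utils::write.csv(edf, epath, row.names = FALSE, quote = FALSE)
      dpath <- file.path(out_dir, sprintf("frames_%03d.csv", k))
      utils::write.csv(attr(ev, "debug"), dpath, row.names = FALSE, quote = FALSE)
      files <- c(files, epath, dpath)
    }
  }
  out <- dplyr::mutate(dplyr::bind_rows(rows),
                       start_error_s = .data$start_s - .data$gt_start_s,
                       duration_error_s = .data$duration_s - .data$gt_duration_s)
  if (!is.null(out_dir)) write_manifest(out_dir, files)
  structure(out, class = c("video_run", class(out)), events = all_events)
}

#' Signal-statistics table for WAV recordings
#'
#' Computes the sensor-comparison statistics ([signal_stats()]) for each WAV
#' file, in the conventional column order: minimum value, maximum value, mean
#' value, dynamic range, crest factor, autocorrelation time. Unreadable files
#' produce a row with `NA` statistics and the error message, plus a warning.
#'
#' @param paths Character vector of WAV file paths.
#' @param out Optional CSV output path.
#' @return A tibble with columns `file`, `minimum`, `maximum`, `mean`,
#'   `dynamic_range_db`, `crest_factor_db`, `autocorrelation_s`, `error`.
#' @export
sensor_stats <- function(paths, out = NULL) {
  assert_that(is.character(paths) && length(paths) > 0, "`paths` must be file paths")
  rows <- lapply(paths, function(p) {
    res <- tryCatch({
      w <- read_wav(p)
      st <- signal_stats.numeric(w$samples, w$sample_rate)
      dplyr::bind_cols(tibble::tibble(file = p), st, tibble::tibble(error = NA_character_))
    }, error = function(e) {
      tibble::tibble(file = p, minimum = NA_real_, maximum = NA_real_,
                     mean = NA_real_, dynamic_range_db = NA_real_,
                     crest_factor_db = NA_real_, autocorrelation_s = NA_real_,
                     error = conditionMessage(e))
    })
    res
  })
  tbl <- dplyr::bind_rows(rows)
  if (any(!is.na(tbl$error))) {
    warning(sprintf("%d file(s) could not be processed", sum(!is.na(tbl$error))))
  }
  if (!is.null(out)) utils::write.csv(tbl, out, row.names = FALSE)
  tbl
}
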