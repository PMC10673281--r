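#' Stratified train/test split
#'
#' Partitions a labeled feature table into disjoint, exhaustive train and
#' test sets, 70/30 by default. Stratification draws each class's share with
#' largest-remainder rounding against a total of `round(train_frac * n)`, so
#' e.g. 600 A + 400 B at 0.7 gives exactly 420 A and 280 B in training.
#' Deterministic under the seed.
#'
#' @param data A data frame with a label column.
#' @param train_frac Training fraction in (0, 1).
#' @param stratify Stratify by class (requires at least two samples per
#'   class).
#' @param seed Integer RNG seed.
#' @param label_col Name of the label column.
#' @return An object of class `dataset_split`: list with `train` and `test`
#'   tibbles.
#' @export
split_dataset <- function(data, train_frac = 0.7, stratify = TRUE, seed = 1L,
                          label_col = "label") {
  assert_that(is.data.frame(data) && nrow(data) >= 2, "`data` must have at least two rows")
  assert_that(label_col %in% names(data), sprintf("no `%s` column in `data`", label_col))
  assert_that(train_frac > 0 && train_frac < 1, "`train_frac` must be in (0, 1)")
  n <- nrow(data)
  total_train <- floor(train_frac * n + 0.5)
  labels <- as.character(data[[label_col]])
  idx_train <- with_seed(seed, {
    if (stratify) {
      tab <- table(labels)
      assert_that(all(tab >= 2),
                  "stratified split needs at least 2 samples per class")
      quota <- train_frac * as.numeric(tab)
      base <- floor(quota)
      rem <- total_train - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      unlist(lapply(seq_along(tab), function(i) {
        rows <- which(labels == names(tab)[i])
        sample(rows, base[i])
      }))
    } else {
      sample(n, total_train)
    }
  })
  structure(list(
    train = tibble::as_tibble(data[sort(idx_train), , drop = FALSE]),
    test = tibble::as_tibble(data[setdiff(seq_len(n), idx_train), , drop = FALSE]),
    seed = as.integer(seed), train_frac = train_frac, stratify = stratify
  ), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (frac %.2f%s, seed %d)\n",
              nrow(x$train), nrow(x$test), x$train_frac,
              if (x$stratify) ", stratified" else "", x$seed))
  invisible(x)
}

feature_columns <- function(data, label_col) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  setdiff(num, c(label_col, "segment", "segment_index"))
}

#' Train an SVM activity classifier
#'
#' Standardizes the features to the training set's mean and variance (stored
#' in the model) and fits a support vector machine. The default kernel is
#' RBF with cost 1 and inverse bandwidth set by the median heuristic
#' (`gamma = 1 / (2 * median pairwise distance^2)` on the standardized
#' training features). The fit is deterministic for fixed input and
#' parameters.
#'
#' @param train Training data frame: one label column plus numeric feature
#'   columns.
#' @param label_col Name of the label column.
#' @param feature_cols Feature column names; defaults to all numeric columns
#'   except the label and any `segment` id column.
#' @param kernel `e1071::svm` kernel (default `"radial"`).
#' @param cost Soft-margin cost C.
#' @param gamma `"median"` for the median heuristic, or a number.
#' @return An object of class `activity_svm`.
#' @seealso [evaluate()], [predict.activity_svm()]
#' @export
train_activity_svm <- function(train, label_col = "label", feature_cols = NULL,
                               kernel = "radial", cost = 1, gamma = "median") {
  assert_that(is.data.frame(train) && nrow(train) >= 2, "`train` must have at least two rows")
  assert_that(label_col %in% names(train), sprintf("no `%s` column in `train`", label_col))
  y <- factor(train[[label_col]])
  assert_that(nlevels(droplevels(y)) >= 2,
              "training set must contain at least two classes")
  y <- droplevels(y)
  if (is.null(feature_cols)) feature_cols <- feature_columns(train, label_col)
  assert_that(length(feature_cols) > 0, "no numeric feature columns found")
  X <- as.matrix(train[, feature_cols, drop = FALSE])
  assert_that(all(is.finite(X)), "features must be finite (no missing values)")
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  if (identical(gamma, "median")) {
    sub <- if (nrow(Xs) > 500) Xs[seq(1, nrow(Xs), length.out = 500), , drop = FALSE] else Xs
    med <- median(dist(sub))
    gamma <- if (is.finite(med) && med > 0) 1 / (2 * med^2) else 1 / ncol(Xs)
  }
  fit <- e1071::svm(x = Xs, y = y, kernel = kernel, cost = cost,
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale,
                 feature_cols = feature_cols, label_col = label_col,
                 levels = levels(y), kernel = kernel, cost = cost,
                 gamma = gamma, n_train = nrow(Xs)),
            class = "activity_svm")
}

#' Predict activity classes
#'
#' @param object An [train_activity_svm()] model.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.activity_svm <- function(object, newdata, ...) {
  assert_that(all(object$feature_cols %in% names(newdata)),
              "newdata is missing model feature columns (dimension mismatch)")
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  predict(object$fit, Xs)
}

#' @export
print.activity_svm <- function(x, ...) {
  cat(sprintf("<activity_svm> %s kernel, C=%g, gamma=%.4g | %d features | classes: %s\n",
              x$kernel, x$cost, x$gamma, length(x$feature_cols),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @method glance activity_svm
#' @export
glance.activity_svm <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, cost = x$cost, gamma = x$gamma,
                 n_features = length(x$feature_cols), n_train = x$n_train,
                 n_support = x$fit$tot.nSV, n_classes = length(x$levels))
}

#' Confusion matrix from truth and prediction
#'
#' @param truth,prediction Vectors of class labels (coerced to a common
#'   factor level set).
#' @return A square count matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, prediction) {
  lev <- union(levels(factor(truth)), levels(factor(prediction)))
  table(truth = factor(truth, lev), prediction = factor(prediction, lev))
}

#' Evaluate a classifier into an accuracy/error report
#'
#' Builds the truth-by-prediction confusion matrix and the derived accuracy
#' (`100 * trace / total`, in percent) and error (`100 - accuracy`) — the
#' standard per-task evaluation surface for weevil-activity classification.
#'
#' @param model An `activity_svm` model.
#' @param data Evaluation data frame with the label column and model
#'   features.
#' @param phase `"testing"` or `"validation"` (bookkeeping only).
#' @return An object of class `classifier_report`: list with `phase`,
#'   `accuracy`, `error`, `confusion`, `n`.
#' @export
evaluate <- function(model, data, phase = c("testing", "validation")) {
  phase <- match.arg(phase)
  assert_that(inherits(model, "activity_svm"), "`model` must be an activity_svm")
  assert_that(is.data.frame(data) && nrow(data) > 0, "`data` must be non-empty")
  assert_that(model$label_col %in% names(data),
              sprintf("no `%s` column in `data`", model$label_col))
  pred <- predict(model, data)
  report_from_confusion(confusion_matrix(data[[model$label_col]], pred), phase)
}

report_from_confusion <- function(cm, phase = "testing") {
  total <- sum(cm)
  acc <- 100 * sum(diag(cm)) / total
  structure(list(phase = phase, accuracy = acc, error = 100 - acc,
                 confusion = cm, n = total),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: accuracy %.2f%%, error %.2f%% (n = %d)\n",
              x$phase, x$accuracy, x$error, x$n))
  print(x$confusion)
  invisible(x)
}

#' @method tidy classifier_report
#' @export
tidy.classifier_report <- function(x, ...) {
  df <- as.data.frame(x$confusion, stringsAsFactors = FALSE)
  tibble::tibble(truth = df$truth, prediction = df$prediction, count = df$Freq)
}

#' @method glance classifier_report
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(phase = x$phase, accuracy = x$accuracy, error = x$error, n = x$n)
}

#' Aggregate per-task accuracies into an overall accuracy
#'
#' Two aggregation conventions are reported side by side: `pooled` (sum of
#' correct counts over sum of evaluated segments across tasks) and
#' `unweighted_mean` (arithmetic mean of the per-task accuracies). With a
#' single report, or reports of equal size, the two coincide.
#'
#' @param reports A list of `classifier_report` objects.
#' @return A tibble with columns `method` and `accuracy` (percent).
#' @export
overall_accuracy <- function(reports) {
  if (inherits(reports, "classifier_report")) reports <- list(reports)
  assert_that(length(reports) >= 1 &&
                all(vapply(reports, inherits, logical(1), "classifier_report")),
              "`reports` must be one or more classifier_report objects")
  correct <- vapply(reports, function(r) sum(diag(r$confusion)), numeric(1))
  totals <- vapply(reports, function(r) r$n, numeric(1))
  accs <- vapply(reports, function(r) r$accuracy, numeric(1))
  tibble::tibble(
    method = c("pooled", "unweighted_mean"),
    accuracy = c(100 * sum(correct) / sum(totals), mean(accs))
  )
}

#' Dominant-band rule classifier
#'
#' A transparent non-learned baseline: a segment is labeled with the activity
#' of its dominant frequency band unless even the winning band holds less
#' than `resting_cutoff` of the spectral power, in which case the segment is
#' called `resting` (broadband noise concentrates in no band). Serves as a
#' floor for the SVM.
#'
#' @param band_tbl Output of [dominant_band()] (data-frame method).
#' @param resting_cutoff Minimum winning in-band power fraction for a
#'   sound-producing call.
#' @return Character vector of predicted activity labels.
#' @export
band_rule_predict <- function(band_tbl, resting_cutoff = 0.5) {
  frac_cols <- grep("^frac_", names(band_tbl), value = TRUE)
  win <- do.call(pmax, band_tbl[frac_cols])
  ifelse(win < resting_cutoff, "resting", band_tbl$band)
}
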