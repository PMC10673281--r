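toy_features <- function(n_a = 30, n_b = 30, sep = 6, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    label = rep(c("a", "b"), c(n_a, n_b)),
    f1 = c(rnorm(n_a), rnorm(n_b) + sep),
    f2 = c(rnorm(n_a), rnorm(n_b) + sep)
  ))
}

test_that("stratified splits use largest-remainder quotas and conserve samples", {
  d <- tibble::tibble(label = rep(c("A", "B"), c(600, 400)), x = rnorm(1000))
  sp <- split_dataset(d, train_frac = 0.7, seed = 3)
  expect_equal(nrow(sp$train), 700)
  expect_equal(nrow(sp$test), 300)
  expect_equal(sum(sp$train$label == "A"), 420)
  expect_equal(sum(sp$train$label == "B"), 280)

  # disjoint and exhaustive
  expect_equal(sort(c(sp$train$x, sp$test$x)), sort(d$x))

  sp2 <- split_dataset(d, train_frac = 0.7, seed = 3)
  expect_identical(sp$train, sp2$train)
  sp3 <- split_dataset(d, train_frac = 0.7, seed = 4)
  expect_false(identical(sp$train, sp3$train))

  tiny <- tibble::tibble(label = c("A", "A", "B"), x = 1:3)
  expect_error(split_dataset(tiny, 0.7), "at least 2 samples per class")
})

test_that("the SVM separates a separable toy set and refits identically", {
  d <- toy_features()
  model <- train_activity_svm(d)
  expect_equal(as.character(predict(model, d)), d$label)

  model2 <- train_activity_svm(d)
  expect_identical(predict(model2, d), predict(model, d))

  one_class <- dplyr::filter(d, label == "a")
  expect_error(train_activity_svm(one_class), "two classes")
  expect_error(predict(model, d["f1"]), "dimension mismatch")
})

test_that("reports derive accuracy and error from the confusion matrix", {
  cm <- matrix(c(9, 2, 1, 8), 2, dimnames = list(truth = c("a", "b"),
                                                 prediction = c("a", "b")))
  rep <- weevilsense:::report_from_confusion(as.table(cm))
  expect_equal(rep$accuracy, 85)
  expect_equal(rep$error, 15)
  expect_equal(rep$n, 20)
  expect_identical(rep$error, 100 - rep$accuracy)

  d <- toy_features()
  sp <- split_dataset(d, seed = 2)
  model <- train_activity_svm(sp$train)
  r <- evaluate(model, sp$test)
  expect_equal(sum(r$confusion), nrow(sp$test))
  expect_identical(r$error, 100 - r$accuracy)
  expect_equal(r$accuracy, 100)

  g <- glance(r)
  expect_equal(g$accuracy, r$accuracy)
  td <- tidy(r)
  expect_equal(sum(td$count), r$n)
})

test_that("overall accuracy reports both aggregation conventions", {
  mk <- function(correct, total) {
    cm <- as.table(matrix(c(correct, total - correct, 0, 0), 2,
                          dimnames = list(truth = c("a", "b"),
                                          prediction = c("a", "b"))))
    weevilsense:::report_from_confusion(cm)
  }
  single <- overall_accuracy(mk(17, 20))
  expect_equal(single$accuracy, c(85, 85))

  # equal totals: pooled equals the unweighted mean
  eq <- overall_accuracy(list(mk(90, 100), mk(80, 100)))
  expect_equal(eq$accuracy[1], eq$accuracy[2])

  three <- overall_accuracy(list(mk(9098, 10000), mk(9706, 10000), mk(9000, 10000)))
  expect_equal(three$accuracy[three$method == "unweighted_mean"], 92.68)
})

test_that("the band rule calls resting when no band dominates", {
  tbl <- tibble::tibble(
    band = c("mating", "pupa_moving"),
    frac_mating = c(0.9, 0.05),
    frac_pupa_moving = c(0.05, 0.3),
    frac_adult_walking = c(0.01, 0.1),
    out_of_band = c(0.04, 0.55)
  )
  expect_equal(band_rule_predict(tbl), c("mating", "resting"))
})
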