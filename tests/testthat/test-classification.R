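test_that("classifier specs enforce their field invariants", {
  expect_error(classifier_spec("svm"), "kernel")
  expect_error(classifier_spec("logistic", kernel = "linear"), "SVM")
  expect_error(classifier_spec("svm", kernel = "linear",
                               complexity = "simple"), "tree")
  expect_silent(classifier_spec("tree", complexity = "complex"))
  expect_equal(classifier_spec("boosted_tree")$label, "Ensemble boosted DT")
})

test_that("linearly separable data is fit perfectly by a linear SVM", {
  set.seed(50)
  x <- rbind(matrix(rnorm(60, -2), 30, 2), matrix(rnorm(60, 2), 30, 2))
  y <- rep(c(0, 1), each = 30)
  pred <- fit_predict(classifier_spec("svm", kernel = "linear"), x, y, x)
  expect_equal(pred, y)
})

test_that("a logistic output of exactly 0.5 goes to the positive class", {
  # a constant feature with balanced labels gives a model whose output is
  # exactly 0.5 everywhere: the documented tie rule assigns class 1
  x <- matrix(0, 4, 1)
  y <- c(0, 1, 0, 1)
  pred <- fit_predict(classifier_spec("logistic"), x, y,
                      matrix(c(0, 3, -3), 3, 1))
  expect_equal(pred, c(1L, 1L, 1L))
})

test_that("a tree on a label-identical binary feature predicts perfectly", {
  set.seed(51)
  y <- rbinom(60, 1, 0.5)
  x <- cbind(y, rnorm(60))
  for (cx in c("simple", "medium", "complex")) {
    pred <- fit_predict(classifier_spec("tree", complexity = cx), x, y, x)
    expect_equal(pred, y)
  }
  pred <- fit_predict(classifier_spec("boosted_tree"), x, y, x)
  expect_equal(pred, y)
})

test_that("single-class training predicts that class", {
  x <- matrix(rnorm(20), 10, 2)
  pred <- fit_predict(classifier_spec("logistic"), x, rep(1, 10), x)
  expect_equal(pred, rep(1, 10))
})

test_that("fits are deterministic", {
  set.seed(52)
  x <- matrix(rnorm(200), 100, 2)
  y <- rbinom(100, 1, 0.5)
  for (spec in default_classifier_menu()) {
    p1 <- fit_predict(spec, x, y, x)
    p2 <- fit_predict(spec, x, y, x)
    expect_identical(p1, p2)
  }
})

test_that("LOOCV accuracy is invariant to duplicating every sample", {
  set.seed(53)
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- as.integer(x[, 1] + rnorm(n, 0, 0.5) > 0)
  spec <- classifier_spec("logistic")
  a1 <- loocv(spec, x, y, selection = "none")
  a2 <- loocv(spec, rbind(x, x), c(y, y), selection = "none")
  expect_lt(abs(a1 - a2), 0.01 + 1e-9)
  expect_error(loocv(spec, x[1:5, ], y[1:5]), "10 samples")
})

test_that("labels independent of features give chance-level LOOCV for every family", {
  set.seed(54)
  n <- 200
  x <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(n, 1, 0.5)
  lo <- 0.5 - 2.58 * sqrt(0.25 / n)
  hi <- 0.5 + 2.58 * sqrt(0.25 / n)
  for (nm in names(default_classifier_menu())) {
    acc <- loocv(default_classifier_menu()[[nm]], x, y, selection = "none")
    expect_gt(acc, lo - 0.02)
    expect_lt(acc, hi + 0.02)
  }
})

test_that("perfectly separable condition effects reach high LOOCV accuracy", {
  set.seed(55)
  n <- 60
  y <- rep(c(0, 1), n / 2)
  x <- cbind(sig = y * 2 + rnorm(n, 0, 0.1),
             noise = rnorm(n))
  acc <- loocv(classifier_spec("svm", kernel = "linear"), x, y)
  expect_gte(acc, 0.95)
})

test_that("fold-internal selection avoids the optimism of full-data selection", {
  # on null data, selecting on the full data then cross-validating is
  # systematically more optimistic than fold-internal selection
  set.seed(56)
  diffs <- replicate(6, {
    n <- 60
    x <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
    y <- rbinom(n, 1, 0.5)
    spec <- classifier_spec("logistic")
    loocv(spec, x, y, selection = "outside") -
      loocv(spec, x, y, selection = "inside")
  })
  expect_gt(mean(diffs), 0)
})

test_that("missing values impute to the session median", {
  x <- matrix(c(1, NA, 3, 10, 20, NA), 3, 2)
  ses <- c("a", "a", "b")
  out <- impute_session_median(x, ses)
  expect_equal(out[2, 1], 1)    # session-a median of feature 1
  expect_equal(out[3, 2], 15)   # falls back to table median
  expect_false(anyNA(out))
})
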