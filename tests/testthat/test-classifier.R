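test_that("a separable two-class toy is fit to training accuracy 1", {
  set.seed(71)
  df <- tibble::tibble(
    x1 = c(rnorm(50), rnorm(50) + 10),
    x2 = rnorm(100),
    stage = rep(c("W", "REM"), each = 50)
  )
  fit <- fit_stager(df, features = c("x1", "x2"),
                    params = model_params(n_estimators = 30))
  expect_equal(mean(predict(fit, df) == df$stage), 1)
})

test_that("single-class and non-finite training data are rejected", {
  df <- tibble::tibble(x1 = rnorm(10), stage = "W")
  expect_error(fit_stager(df, features = "x1"), "two classes")
  df2 <- tibble::tibble(x1 = c(rnorm(9), NA), stage = rep(c("W", "N1"), 5))
  expect_error(fit_stager(df2, features = "x1"), "non-finite")
})

test_that("refitting with the same seed reproduces held-out predictions", {
  df <- toy_features(n_subjects = 4, epochs_per_stage = 6, seed = 72)
  probe <- toy_features(n_subjects = 2, epochs_per_stage = 4, seed = 73)
  p <- model_params(n_estimators = 40)
  f1 <- fit_stager(df, params = p)
  f2 <- fit_stager(df, params = p)
  expect_identical(predict(f1, probe), predict(f2, probe))
})

test_that("prediction aligns columns by name and errors when one is missing", {
  df <- toy_features(n_subjects = 4, epochs_per_stage = 6, seed = 74)
  fit <- fit_stager(df, params = model_params(n_estimators = 30))
  shuffled <- df[, rev(names(df))]
  expect_identical(predict(fit, df), predict(fit, shuffled))
  expect_error(predict(fit, df[, -match("inf_1", names(df))]), "inf_1")
})

test_that("predicted labels come from the training alphabet", {
  df <- toy_features(n_subjects = 3, epochs_per_stage = 5, seed = 75)
  fit <- fit_stager(df, params = model_params(n_estimators = 20))
  expect_true(all(predict(fit, df) %in% stage_levels()))
  prob <- predict(fit, df, type = "prob")
  expect_equal(colnames(prob), stage_levels())
  expect_equal(unname(rowSums(prob)), rep(1, nrow(df)), tolerance = 1e-6)
})

test_that("grid search returns the single combination when there is one", {
  df <- toy_features(n_subjects = 4, epochs_per_stage = 4, seed = 76)
  gs <- grid_search(df, df, list(max_depth = 3L),
                    base = model_params(n_estimators = 10))
  expect_equal(gs$best$max_depth, 3L)
  expect_equal(nrow(gs$results), 1)
  expect_error(grid_search(df, df, list()), "empty")
})

test_that("a degenerate learning rate loses the grid search", {
  # an interaction task (XOR of two features): a vanishing learning rate
  # freezes the ensemble near its first arbitrary tree and cannot learn it
  set.seed(77)
  mk <- function(n) {
    x1 <- rnorm(n); x2 <- rnorm(n)
    tibble::tibble(x1 = x1, x2 = x2,
                   stage = ifelse(xor(x1 > 0, x2 > 0), "W", "N2"))
  }
  learn <- mk(1000)
  val <- mk(400)
  base <- model_params(n_estimators = 100, max_depth = 3,
                       colsample_bytree = 1, subsample = 1)
  gs <- grid_search(learn, val, list(learning_rate = c(1e-6, 0.2)),
                    base = base)
  expect_equal(gs$best$learning_rate, 0.2)
})

test_that("grid-search ties go to the earlier combination", {
  df <- toy_features(n_subjects = 4, epochs_per_stage = 5, sep = 8, seed = 78)
  # both depths reach 100% on trivially separable data -> first wins
  gs <- grid_search(df, df, list(max_depth = c(4L, 6L)),
                    base = model_params(n_estimators = 20))
  expect_equal(gs$best$max_depth, 4L)
})

test_that("default parameters are the tuned operating point", {
  p <- model_params()
  expect_equal(p$colsample_bytree, 0.8)
  expect_equal(p$learning_rate, 0.2)
  expect_equal(p$max_depth, 7L)
  expect_equal(p$n_estimators, 300L)
  expect_equal(p$reg_alpha, 0.1)
  expect_equal(p$reg_lambda, 1)
  expect_equal(p$subsample, 0.8)
})
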