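test_that("Fisher components match the two-class worked example", {
  df <- tibble::tibble(f = c(1, 3, 5, 7), stage = c("a", "a", "b", "b"))
  sc <- fisher_scores(df, features = "f")
  expect_equal(sc$s_b, 4)
  expect_equal(sc$s_w, 1)
  expect_equal(sc$j, 4)
})

test_that("a constant feature scores 0 and a separating one scores Inf", {
  df <- tibble::tibble(const = rep(2, 6), sep = c(1, 1, 1, 9, 9, 9),
                       stage = rep(c("a", "b"), each = 3))
  sc <- fisher_scores(df, features = c("const", "sep"))
  expect_equal(sc$j[sc$feature == "const"], 0)
  expect_equal(sc$j[sc$feature == "sep"], Inf)
})

test_that("Fisher score is invariant under affine transforms", {
  set.seed(61)
  df <- tibble::tibble(f = rnorm(60) + rep(c(0, 2, 4), 20),
                       stage = rep(c("a", "b", "c"), 20))
  j0 <- fisher_scores(df, features = "f")$j
  df$f <- -3.7 * df$f + 11
  j1 <- fisher_scores(df, features = "f")$j
  expect_equal(j1, j0, tolerance = 1e-9)
})

test_that("S_W + S_B equals the population variance (law of total variance)", {
  set.seed(62)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    df <- tibble::tibble(
      f1 = rnorm(n), f2 = rexp(n), f3 = runif(n),
      stage = sample(stage_levels(), n, replace = TRUE)
    )
    sc <- fisher_scores(df, features = c("f1", "f2", "f3"))
    for (k in 1:3) {
      total <- pop_var(df[[k]])
      expect_equal(sc$s_w[k] + sc$s_b[k], total, tolerance = 1e-9 * total)
    }
  }
})

test_that("single-class data is rejected", {
  df <- tibble::tibble(f = rnorm(10), stage = "W")
  expect_error(fisher_scores(df, features = "f"), "two classes")
})

test_that("the prefilter keeps the boundary and falls back when empty", {
  sc <- tibble::tibble(feature = c("a", "b", "c"), s_b = 1, s_w = 1,
                       j = c(0.05, 0.1, 4.0))
  expect_equal(prefilter_features(sc, 0.1), c(FALSE, TRUE, TRUE))
  expect_equal(prefilter_features(sc, 0), rep(TRUE, 3))
  expect_warning(m <- prefilter_features(sc, 100), "top 10")
  expect_equal(sum(m), 3)  # fewer than 10 features exist
})

test_that("importance ranking puts a perfectly separating feature first", {
  set.seed(63)
  n <- 200
  df <- tibble::tibble(stage = rep(c("W", "N2"), each = n / 2))
  df$sep <- ifelse(df$stage == "W", 0, 10) + rnorm(n, sd = 0.1)
  for (i in 1:9) df[[paste0("noise_", i)]] <- rnorm(n)
  feats <- setdiff(names(df), "stage")
  rk <- importance_rank(df, feats, params = model_params(n_estimators = 50))
  expect_equal(rk$feature[1], "sep")
  # determinism under a fixed seed
  rk2 <- importance_rank(df, feats, params = model_params(n_estimators = 50))
  expect_identical(rk, rk2)
})

test_that("duplicate informative columns rank without error, ties by index", {
  set.seed(64)
  n <- 120
  df <- tibble::tibble(stage = rep(c("W", "N3"), each = n / 2))
  df$a <- ifelse(df$stage == "W", 0, 5) + rnorm(n, sd = 0.1)
  df$b <- df$a
  df$zero1 <- rnorm(n)
  df$zero2 <- rnorm(n)
  rk <- importance_rank(df, c("a", "b", "zero1", "zero2"),
                        params = model_params(n_estimators = 20))
  expect_equal(nrow(rk), 4)
  unused <- rk[rk$gain == 0, ]
  expect_equal(unused$feature, sort(unused$feature))  # index order on ties
})

test_that("top-k selection clamps to the ranking length", {
  rk <- tibble::tibble(feature = letters[1:10], gain = 10:1, rank = 1:10)
  expect_length(select_top_k(rk, 25), 10)
  expect_length(select_top_k(rk, 4), 4)
  expect_equal(select_top_k(rk, 4), letters[1:4])
  expect_error(select_top_k(rk, 0), "positive")
})

test_that("two-step selection keeps k features and is internally consistent", {
  df <- toy_features(n_subjects = 6, epochs_per_stage = 6, n_informative = 30,
                     n_noise = 10, sep = 3, seed = 65)
  cfg <- stager_config(top_k = 25)
  cfg$model$n_estimators <- 50L
  sel <- select_features(df, cfg)
  expect_s3_class(sel, "feature_selection")
  expect_length(sel$selected, 25)
  td <- tidy(sel)
  expect_true(all(td$feature[td$selected] %in% td$feature[td$survived]))
  expect_gte(sum(td$survived), 25)
})

test_that("accuracy-vs-k curve has one row per k and high accuracy on separable data", {
  df <- toy_features(n_subjects = 6, epochs_per_stage = 6, sep = 5, seed = 66)
  feats <- c(paste0("inf_", 1:3), paste0("noise_", 1:5))
  learn <- df[df$subject_id <= "T04", ]
  val <- df[df$subject_id > "T04", ]
  rk <- importance_rank(learn, feats, params = model_params(n_estimators = 30))
  curve <- accuracy_vs_k_curve(learn, val, rk, k_grid = c(3, 8),
                               params = model_params(n_estimators = 30))
  expect_equal(nrow(curve), 2)
  expect_true(all(is.finite(curve$accuracy)))
  expect_gt(curve$accuracy[curve$k == 8], 90)
})
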