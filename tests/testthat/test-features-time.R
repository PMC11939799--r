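test_that("time-domain features on a constant signal are degenerate zeros", {
  f <- time_domain_features(rep(5, 100))
  expect_equal(f$range, 0)
  expect_equal(f$mean, 5)
  expect_equal(f$variance, 0)
  expect_equal(f$std, 0)
  expect_equal(f$peak_count, 0)
  expect_equal(f$zero_crossings, 0)
  expect_equal(f$diff_variance, 0)
})

test_that("peaks and zero crossings follow the strict rules (hand oracle)", {
  # x = [0,1,0,-1,0,1]: products at sign changes 1*-1 (idx2-3... ) -> 2
  # crossings; one strict local maximum (the first 1)
  f <- time_domain_features(c(0, 1, 0, -1, 0, 1))
  expect_equal(f$zero_crossings, 2)
  expect_equal(f$peak_count, 1)
})

test_that("range of a sampled unit sine cycle is close to 2", {
  x <- sin(2 * pi * seq(0, 99) / 100)
  f <- time_domain_features(x)
  expect_lt(abs(f$range - 2), 1e-3)
})

test_that("variance and std are population quantities and consistent", {
  set.seed(1)
  x <- rnorm(257)
  f <- time_domain_features(x)
  expect_equal(f$variance, pop_var(x))
  expect_equal(f$std, sqrt(pop_var(x)))
})

test_that("difference variance matches direct evaluation", {
  expect_equal(difference_variance(3 * (0:49)), 0)       # constant differences
  # x = [0,2,0,2]: D = [2,-2,2], mean 2/3, popvar = 32/9
  expect_equal(difference_variance(c(0, 2, 0, 2)), 32 / 9)
  expect_error(difference_variance(5), "too short")
})

test_that("difference variance of white noise is about twice its variance", {
  set.seed(9)
  sigma <- 3
  x <- rnorm(3000, sd = sigma)
  dv <- difference_variance(x)
  expect_lt(abs(dv - 2 * sigma^2) / (2 * sigma^2), 0.1)
})

test_that("a qualifying biphasic deflection is detected once", {
  # 160 uV p2p, extrema 0.5 s apart, quiet baseline
  x <- planted_eog(1, p2p = 160, extrema_gap_s = 0.5)
  ev <- detect_large_eye_movements(x, 100)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$p2p_uV, 120)
  expect_lte(ev$duration_s, 1.5)
})

test_that("sub-threshold amplitude or slow deflections yield no events", {
  x_small <- planted_eog(1, p2p = 100, extrema_gap_s = 0.5)
  expect_equal(nrow(detect_large_eye_movements(x_small, 100)), 0)
  x_slow <- planted_eog(1, p2p = 160, extrema_gap_s = 2.0)
  expect_equal(nrow(detect_large_eye_movements(x_slow, 100)), 0)
})

test_that("planted-event recovery is exact for k = 0..5", {
  for (k in 0:5) {
    x <- planted_eog(k, p2p = 200, extrema_gap_s = 0.5, seed = 100 + k)
    ev <- detect_large_eye_movements(x, 100)
    expect_equal(nrow(ev), k, info = paste("k =", k))
    if (k > 0) {
      expect_true(all(ev$p2p_uV > 120))
      expect_true(all(ev$duration_s <= 1.5))
    }
  }
})

test_that("empty or short signals give an empty event table", {
  expect_equal(nrow(detect_large_eye_movements(numeric(0), 100)), 0)
  expect_equal(nrow(detect_large_eye_movements(rnorm(10), 100)), 0)
})

test_that("excluding events lowers the difference variance of spiky EOG", {
  x <- planted_eog(3, p2p = 250, extrema_gap_s = 0.5, seed = 5)
  ev <- detect_large_eye_movements(x, 100)
  expect_equal(nrow(ev), 3)
  expect_lt(diff_variance_excluding_lem(x, 100, ev), difference_variance(x))
})

test_that("exclusion with no events equals the plain difference variance", {
  set.seed(2)
  x <- rnorm(3000)
  no_ev <- detect_large_eye_movements(rep(0, 10), 100)  # empty table
  expect_equal(diff_variance_excluding_lem(x, 100, no_ev), difference_variance(x))
})

test_that("events covering the whole epoch give 0 with a warning", {
  x <- rnorm(300)
  ev <- tibble::tibble(start_idx = 1L, end_idx = 300L,
                       p2p_uV = 200, duration_s = 1)
  expect_warning(out <- diff_variance_excluding_lem(x, 100, ev), "removed")
  expect_equal(out, 0)
})

test_that("differences never span a cut (segment pooling oracle)", {
  # two flat segments at different levels separated by one removed event:
  # pooled within-segment differences are all zero, despite the level jump
  x <- c(rep(0, 200), rep(1000, 100), rep(50, 200))
  ev <- tibble::tibble(start_idx = 201L, end_idx = 300L,
                       p2p_uV = 1000, duration_s = 0.5)
  expect_equal(diff_variance_excluding_lem(x, 100, ev, pad_s = 0.5), 0)
})
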