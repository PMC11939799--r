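flat_psd <- function(fs = 100, df = 0.1) {
  f <- seq(0, fs / 2, by = df)
  structure(list(freqs = f, density = rep(1, length(f)), ar_order = 16L),
            class = "yw_psd")
}

test_that("Yule-Walker PSD peak matches the analytic AR(2) spectrum peak", {
  # fit at the generating order so the oracle isolates the estimator (the
  # broad AR(2) peak wobbles by over 1 Hz under heavy over-parameterisation)
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = c(0.75, -0.5)), n = 3000))
  psd <- yule_walker_psd(x, fs = 100, order = 2)
  est_peak <- psd$freqs[which.max(psd$density)]
  true_peak <- ar2_peak_freq(0.75, -0.5, fs = 100)
  expect_lt(abs(est_peak - true_peak), 0.5)
})

test_that("white-noise spectrum is flat at order 16", {
  set.seed(12)
  psd <- yule_walker_psd(rnorm(3000), fs = 100, order = 16)
  sel <- psd$freqs >= 1 & psd$freqs <= 40
  expect_lt(max(psd$density[sel]) / min(psd$density[sel]), 3)
})

test_that("degenerate inputs are rejected", {
  expect_error(yule_walker_psd(rep(1, 3000), 100), "singular")
  expect_error(yule_walker_psd(rnorm(10), 100, order = 16), "longer than")
})

test_that("band power integrates the density (additivity, totality)", {
  psd <- flat_psd()
  expect_equal(band_power(psd, 0, 50), 50)       # unit density
  p_ab <- band_power(psd, 2, 8)
  expect_lt(abs(band_power(psd, 2, 5) + band_power(psd, 5, 8) - p_ab) / p_ab,
            1e-9)
  expect_error(band_power(psd, 8, 2), "inverted")
  expect_error(band_power(psd, 40, 60), "outside")
})

test_that("a pure 10 Hz tone concentrates power in alpha", {
  set.seed(13)
  t <- seq_len(3000) / 100
  x <- sin(2 * pi * 10 * t) + 0.02 * rnorm(3000)
  psd <- yule_walker_psd(x, 100)
  expect_gt(band_power(psd, 8, 12) / band_power(psd, 0, 50), 0.9)
  r <- absolute_band_power_ratios(psd)
  expect_gt(r[["abs_alpha"]], 0.9)
  expect_lt(r[["abs_delta"]], 0.05)
})

test_that("absolute ratios are in [0,1] and disjoint classics sum below 1", {
  set.seed(14)
  psd <- yule_walker_psd(rnorm(3000), 100)
  r <- absolute_band_power_ratios(psd)
  expect_true(all(r >= 0 & r <= 1))
  expect_lte(sum(r[c("abs_delta", "abs_theta", "abs_alpha", "abs_beta")]),
             1 + 1e-9)
})

test_that("a 1 Hz tone loads the K-complex band", {
  set.seed(15)
  t <- seq_len(3000) / 100
  x <- sin(2 * pi * 1 * t) + 0.02 * rnorm(3000)
  r <- absolute_band_power_ratios(yule_walker_psd(x, 100))
  expect_gt(r[["abs_kcomplex"]], 0.5)
})

test_that("relative ratios on a flat spectrum equal bandwidth ratios", {
  r <- relative_power_ratios(flat_psd())
  expect_equal(r[["ratio_delta_theta"]], 3.5 / 4, tolerance = 1e-9)
  expect_equal(r[["ratio_theta_alpha"]], 1, tolerance = 1e-9)
  expect_equal(r[["ratio_alpha_beta"]], 4 / 18, tolerance = 1e-9)
  expect_equal(r[["ratio_slow_fast"]], 7.5 / 22, tolerance = 1e-9)
})

test_that("tone-dominated spectra drive the relative ratios", {
  set.seed(16)
  t <- seq_len(3000) / 100
  r2 <- relative_power_ratios(
    yule_walker_psd(sin(2 * pi * 2 * t) + 0.02 * rnorm(3000), 100))
  expect_gt(r2[["ratio_delta_theta"]], 5)
  r10 <- relative_power_ratios(
    yule_walker_psd(sin(2 * pi * 10 * t) + 0.02 * rnorm(3000), 100))
  expect_lt(r10[["ratio_slow_fast"]], 0.2)
})

test_that("EOG ratios respond to slow vs rapid tones and stay bounded", {
  set.seed(17)
  t <- seq_len(3000) / 100
  r1 <- eog_power_ratios(yule_walker_psd(sin(2 * pi * 1 * t) + 0.02 * rnorm(3000), 100))
  expect_gt(r1[["eog_slow_ratio"]], 0.8)
  r3 <- eog_power_ratios(yule_walker_psd(sin(2 * pi * 3 * t) + 0.02 * rnorm(3000), 100))
  expect_gt(r3[["eog_rapid_ratio"]], 0.8)
  expect_lte(r1[["eog_slow_ratio"]] + r1[["eog_rapid_ratio"]], 1 + 1e-9)
})

test_that("all ratio features are amplitude-scale invariant", {
  set.seed(18)
  x <- rnorm(3000)
  p1 <- yule_walker_psd(x, 100)
  p2 <- yule_walker_psd(7.3 * x, 100)
  expect_equal(absolute_band_power_ratios(p1), absolute_band_power_ratios(p2),
               tolerance = 1e-9)
  expect_equal(relative_power_ratios(p1), relative_power_ratios(p2),
               tolerance = 1e-9)
  expect_equal(eog_power_ratios(p1), eog_power_ratios(p2), tolerance = 1e-9)
})
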