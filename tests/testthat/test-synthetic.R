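test_that("stage profiles shape the spectrum: N3 is delta-dominant, W alpha-dominant", {
  set.seed(101)
  w <- synth_eeg_epoch("W")
  n3 <- synth_eeg_epoch("N3")
  rw <- absolute_band_power_ratios(yule_walker_psd(wavelet_denoise(w), 100))
  rn <- absolute_band_power_ratios(yule_walker_psd(wavelet_denoise(n3), 100))
  expect_gt(rn[["abs_delta"]], rw[["abs_delta"]])
  expect_gt(rw[["abs_alpha"]], rw[["abs_delta"]])
})

test_that("a zeroed profile produces pure white noise", {
  prof <- stage_profiles()$W
  prof$band_uV[] <- 0
  prof$lem_rate <- 0
  prof$spindle_rate <- 0
  prof$kcomplex_rate <- 0
  prof$noise_uV <- 1
  set.seed(102)
  x <- synth_eeg_epoch("W", prof)
  expect_equal(sd(x), 1, tolerance = 0.1)
  psd <- yule_walker_psd(x, 100)
  sel <- psd$freqs >= 1 & psd$freqs <= 40
  expect_lt(max(psd$density[sel]) / min(psd$density[sel]), 3)
})

test_that("planted REM eye movements are recovered exactly; N3 has none", {
  set.seed(103)
  rem <- synth_eog_epoch("REM", n_events = 3)
  expect_equal(nrow(rem$events), 3)
  den <- wavelet_denoise(rem$signal)
  ev <- detect_large_eye_movements(den, 100)
  expect_equal(nrow(ev), 3)
  n3 <- synth_eog_epoch("N3", seed = 104)
  expect_equal(nrow(detect_large_eye_movements(wavelet_denoise(n3$signal), 100)), 0)
})

test_that("N1 slow movements stay smoother than raw REM activity", {
  set.seed(105)
  n1 <- synth_eog_epoch("N1")$signal
  rem <- synth_eog_epoch("REM", n_events = 3)$signal
  ev_n1 <- detect_large_eye_movements(wavelet_denoise(n1), 100)
  dv_n1 <- diff_variance_excluding_lem(wavelet_denoise(n1), 100, ev_n1)
  expect_lt(dv_n1, difference_variance(wavelet_denoise(rem)))
})

test_that("multi-subject simulation is reproducible with distinct subjects", {
  tmpl <- make_stage_template(lead_wake_min = 2, trail_wake_min = 2, cycles = 1)[1:20]
  es1 <- simulate_psg(n_subjects = 2, seed = 9, template = tmpl, trim = FALSE)
  es2 <- simulate_psg(n_subjects = 2, seed = 9, template = tmpl, trim = FALSE)
  expect_equal(sort(unique(es1$meta$subject_id)), c("S01", "S02"))
  expect_identical(es1$eeg, es2$eeg)
  es3 <- simulate_psg(n_subjects = 2, seed = 10, template = tmpl, trim = FALSE)
  expect_false(identical(es1$eeg, es3$eeg))
})

test_that("45 min of leading wake loses exactly 30 epochs to the trim", {
  tmpl <- make_stage_template(lead_wake_min = 45, trail_wake_min = 10, cycles = 1)
  syn <- synth_recording("TR", template = tmpl, seed = 106)
  es <- segment_epochs(syn$recording, syn$hypnogram)
  tr <- trim_wake_periphery(es)
  expect_equal(nrow(es$meta) - nrow(tr$meta), 30)
  expect_equal(rle(tr$meta$stage)$lengths[1], 60)
})

test_that("key discriminative features survive the Fisher prefilter", {
  # 200 epochs per stage; compute just the two features under test
  set.seed(107)
  n_per <- 200
  stages <- stage_levels()
  vals <- purrr::map_dfr(stages, function(st) {
    purrr::map_dfr(seq_len(n_per), function(i) {
      eeg <- wavelet_denoise(synth_eeg_epoch(st))
      eog <- wavelet_denoise(synth_eog_epoch(st)$signal)
      tibble::tibble(
        stage = st,
        abs_delta = absolute_band_power_ratios(
          yule_walker_psd(eeg, 100))[["abs_delta"]],
        lem_count = nrow(detect_large_eye_movements(eog, 100))
      )
    })
  })
  sc <- fisher_scores(vals, features = c("abs_delta", "lem_count"))
  expect_gt(sc$j[sc$feature == "abs_delta"], 0.1)
  expect_gt(sc$j[sc$feature == "lem_count"], 0.1)
})
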