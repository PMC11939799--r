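test_that("a 60 s zero recording round-trips with 6000 samples per channel", {
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf_recording(p, numeric(6000), numeric(6000), fs = 100)
  rec <- read_edf_recording(p)
  expect_length(rec$eeg, 6000)
  expect_length(rec$eog, 6000)
  expect_equal(rec$fs, 100)
})

test_that("sine content survives the 16-bit round trip within quantisation", {
  p <- withr::local_tempfile(fileext = ".edf")
  t <- seq_len(6000) / 100
  eeg <- 50 * sin(2 * pi * 2 * t)
  eog <- 120 * sin(2 * pi * 0.5 * t)
  write_edf_recording(p, eeg, eog, fs = 100)
  rec <- read_edf_recording(p)
  # quantisation step = 2 * phys_max / 65535
  expect_lt(max(abs(rec$eeg - eeg)), 2 * 50 / 65535 * 1.01)
  expect_lt(max(abs(rec$eog - eog)), 2 * 120 / 65535 * 1.01)
})

test_that("requesting an absent channel names the channel in the error", {
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf_recording(p, numeric(3000), numeric(3000), fs = 100,
                      eeg_label = "EEG Pz-Oz")
  expect_error(read_edf_recording(p, eeg_channel = "EEG Fpz-Cz"), "Fpz-Cz")
  expect_error(read_edf_recording("/nonexistent.edf"), "not found")
})

test_that("hypnograms round-trip through EDF+ annotations", {
  p <- withr::local_tempfile(fileext = ".edf")
  hyp <- tibble::tibble(
    onset_s = c(0, 300, 420),
    duration_s = c(300, 120, 600),
    raw_stage = c("Sleep stage W", "Sleep stage 1", "Sleep stage 2")
  )
  write_hypnogram_edf(p, hyp)
  back <- read_hypnogram(p)
  expect_equal(back$onset_s, hyp$onset_s)
  expect_equal(back$duration_s, hyp$duration_s)
  expect_equal(back$raw_stage, hyp$raw_stage)
})

test_that("CSV hypnograms are accepted with the documented columns", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(onset_s = c(0, 60), duration_s = c(60, 30),
                       stage = c("Sleep stage W", "Sleep stage R")),
            p, row.names = FALSE)
  hyp <- read_hypnogram(p)
  expect_equal(hyp$raw_stage[2], "Sleep stage R")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), p2, row.names = FALSE)
  expect_error(read_hypnogram(p2), "onset_s")
})

test_that("synthetic recordings round-trip: labels and amplitudes agree", {
  d <- withr::local_tempdir()
  syn <- synth_recording("RT1", template = c(rep("W", 3), "N2", "N2", "REM"),
                         seed = 41)
  write_edf_recording(file.path(d, "RT1-PSG.edf"), syn$recording$eeg,
                      syn$recording$eog, 100)
  write_hypnogram_edf(file.path(d, "RT1-Hypnogram.edf"), syn$hypnogram)
  rec <- read_edf_recording(file.path(d, "RT1-PSG.edf"), subject_id = "RT1")
  hyp <- read_hypnogram(file.path(d, "RT1-Hypnogram.edf"))
  es_disk <- segment_epochs(rec, hyp)
  es_mem <- segment_epochs(syn$recording, syn$hypnogram)
  expect_equal(es_disk$meta$stage, es_mem$meta$stage)
  q <- 2 * max(abs(syn$recording$eeg)) / 65535
  expect_lt(max(abs(es_disk$eeg - es_mem$eeg)), 1.5 * q)
})
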