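# Synthetic polysomnography with stage-dependent spectral profiles and
# planted eye-movement events, so the whole pipeline is testable offline.

#' Stage-dependent generation profiles
#'
#' Per stage: the EEG amplitude (microvolt SD) assigned to band-limited
#' noise in each rhythm band, transient rates (events per 30 s epoch) for
#' sleep spindles and K-complexes, and EOG event rates/amplitudes. Defaults
#' encode the textbook stage signatures the features exploit: wake is
#' alpha-dominant with frequent large eye movements; N1 theta-dominant with
#' slow sub-threshold eye movements; N2 carries spindles and K-complexes;
#' N3 is delta-dominant with a quiescent EOG; REM mixes sawtooth/theta EEG
#' with supra-threshold rapid eye movements.
#'
#' @return named list (one entry per stage) of profile lists.
#' @export
stage_profiles <- function() {
  bw <- function(delta, theta, alpha, beta, spindle, kcomplex, sawtooth) {
    c(delta = delta, theta = theta, alpha = alpha, beta = beta,
      spindle = spindle, kcomplex = kcomplex, sawtooth = sawtooth)
  }
  list(
    W = list(band_uV = bw(6, 5, 20, 6, 2, 3, 4), noise_uV = 3,
             spindle_rate = 0, kcomplex_rate = 0,
             lem_rate = 2, sem_rate = 0, lem_amp_uV = c(95, 130),
             eog_bg_uV = 10),
    N1 = list(band_uV = bw(10, 16, 5, 3, 2, 5, 9), noise_uV = 3,
              spindle_rate = 0, kcomplex_rate = 0,
              lem_rate = 0, sem_rate = 1.5, lem_amp_uV = c(95, 130),
              eog_bg_uV = 12),
    N2 = list(band_uV = bw(16, 12, 4, 3, 4, 8, 8), noise_uV = 3,
              spindle_rate = 1.5, kcomplex_rate = 1,
              lem_rate = 0, sem_rate = 0, lem_amp_uV = c(95, 130),
              eog_bg_uV = 6),
    N3 = list(band_uV = bw(45, 8, 3, 2, 2, 20, 10), noise_uV = 3,
              spindle_rate = 0.3, kcomplex_rate = 2,
              lem_rate = 0, sem_rate = 0, lem_amp_uV = c(95, 130),
              eog_bg_uV = 5),
    REM = list(band_uV = bw(8, 14, 4, 5, 1, 4, 18), noise_uV = 3,
               spindle_rate = 0, kcomplex_rate = 0,
               lem_rate = 2, sem_rate = 0, lem_amp_uV = c(95, 130),
               eog_bg_uV = 10)
  )
}

# band-limited Gaussian noise with target SD, generated by FFT masking
.band_noise <- function(n, fs, lo, hi, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  W[f < lo | f > hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd_target
}

# windowed transient: a 13 Hz spindle burst or a slow biphasic K-complex
.spindle_burst <- function(n, fs, amp = 30) {
  len <- round(1.0 * fs)
  t <- seq_len(len) / fs
  amp * sin(2 * pi * 13 * t) * (0.5 - 0.5 * cos(2 * pi * seq_len(len) / len))
}

.kcomplex_wave <- function(n, fs, amp = 75) {
  len <- round(1.0 * fs)
  t <- seq_len(len) / fs
  amp * sin(2 * pi * 1 * t) * (0.5 - 0.5 * cos(2 * pi * seq_len(len) / len))
}

.add_transients <- function(x, fs, rate, waveform_fun, amp) {
  k <- stats::rpois(1, rate)
  n <- length(x)
  for (i in seq_len(k)) {
    w <- waveform_fun(n, fs, amp)
    start <- sample.int(n - length(w), 1)
    x[start:(start + length(w) - 1L)] <- x[start:(start + length(w) - 1L)] + w
  }
  x
}

#' Synthesise one EEG epoch
#'
#' Sum of band-limited Gaussian noise components weighted by the stage
#' profile, plus planted spindle/K-complex transients and white measurement
#' noise.
#'
#' @param stage stage label (W/N1/N2/N3/REM).
#' @param profile profile list for the stage (see [stage_profiles()]).
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch length in seconds.
#' @param seed optional RNG seed for a reproducible single epoch.
#' @return numeric vector of `fs * epoch_s` samples (microvolts).
#' @export
synth_eeg_epoch <- function(stage, profile = stage_profiles()[[stage]],
                            fs = 100, epoch_s = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- fs * epoch_s
  bands <- eeg_bands()
  x <- stats::rnorm(n, sd = profile$noise_uV)
  for (i in seq_len(nrow(bands))) {
    x <- x + .band_noise(n, fs, bands$lo[i], bands$hi[i],
                         profile$band_uV[[bands$band[i]]])
  }
  if (profile$spindle_rate > 0) {
    x <- .add_transients(x, fs, profile$spindle_rate, .spindle_burst, 30)
  }
  if (profile$kcomplex_rate > 0) {
    x <- .add_transients(x, fs, profile$kcomplex_rate, .kcomplex_wave, 75)
  }
  x
}

# one biphasic deflection: A sin(2 pi t / T) over [0, T]; extrema at T/4 and
# 3T/4 (interval T/2), peak-to-peak 2A
.biphasic <- function(fs, period_s, amp) {
  len <- round(period_s * fs)
  amp * sin(2 * pi * seq_len(len) / len)
}

#' Synthesise one EOG epoch with ground-truth events
#'
#' Low-frequency background noise plus planted biphasic deflections. Wake
#' and REM epochs receive large eye movements (peak-to-peak above 120
#' microvolts, extrema about 0.5 s apart); N1 epochs receive slow
#' sub-threshold movements. Planted events are returned as exact ground
#' truth so detector tests can be exact rather than statistical.
#'
#' @inheritParams synth_eeg_epoch
#' @param n_events override the Poisson event count (e.g. to plant exactly
#'   k qualifying deflections).
#' @return list with `signal` (numeric) and `events` (tibble `start_s`,
#'   `end_s`, `p2p_uV`, one row per planted large eye movement).
#' @export
synth_eog_epoch <- function(stage, profile = stage_profiles()[[stage]],
                            fs = 100, epoch_s = 30, seed = NULL,
                            n_events = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- fs * epoch_s
  x <- .band_noise(n, fs, 0.2, 1.5, profile$eog_bg_uV) + stats::rnorm(n, sd = 2)
  events <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                           p2p_uV = numeric(0))
  place_events <- function(k, period_range, amp_range) {
    placed <- 0L
    spans <- matrix(numeric(0), 0, 2)
    guard <- 0L
    while (placed < k && guard < 200L) {
      guard <- guard + 1L
      period <- stats::runif(1, period_range[1], period_range[2])
      amp <- stats::runif(1, amp_range[1], amp_range[2])
      w <- .biphasic(fs, period, amp)
      start <- sample.int(n - length(w) - 2L * fs, 1) + fs  # keep off edges
      span <- c(start - 1.5 * fs, start + length(w) + 1.5 * fs)
      if (nrow(spans) > 0 &&
          any(span[1] < spans[, 2] & span[2] > spans[, 1])) next
      spans <- rbind(spans, span)
      x[start:(start + length(w) - 1L)] <<- x[start:(start + length(w) - 1L)] + w
      placed <- placed + 1L
      events <<- dplyr::bind_rows(events, tibble::tibble(
        start_s = start / fs, end_s = (start + length(w)) / fs, p2p_uV = 2 * amp
      ))
    }
  }
  if (profile$lem_rate > 0 || !is.null(n_events)) {
    k <- n_events %||% stats::rpois(1, profile$lem_rate)
    place_events(k, c(0.9, 1.2), profile$lem_amp_uV)
  }
  if (profile$sem_rate > 0) {
    k <- stats::rpois(1, profile$sem_rate)
    if (k > 0) {
      for (i in seq_len(k)) {
        w <- .biphasic(fs, stats::runif(1, 3.2, 3.8), stats::runif(1, 25, 40))
        start <- sample.int(n - length(w) - 2L * fs, 1) + fs
        x[start:(start + length(w) - 1L)] <- x[start:(start + length(w) - 1L)] + w
      }
    }
  }
  list(signal = x, events = events)
}

#' Default overnight stage sequence
#'
#' A plausible night at epoch resolution: `lead_wake_min` minutes of wake,
#' `cycles` sleep cycles of N1 -> N2 -> N3 -> N2 -> REM, then
#' `trail_wake_min` minutes of wake. With the defaults (45 min wake on each
#' side, 4 cycles) the night is 700 epochs, and the peripheral wake exceeds
#' the 30 min trimming margin by 15 min on each side.
#'
#' @param lead_wake_min,trail_wake_min peripheral wake in minutes.
#' @param cycles number of sleep cycles.
#' @return character vector of stage labels, one per 30 s epoch.
#' @export
make_stage_template <- function(lead_wake_min = 45, trail_wake_min = 45,
                                cycles = 4L) {
  cycle <- c(rep("N1", 12), rep("N2", 40), rep("N3", 28),
             rep("N2", 20), rep("REM", 30))
  c(rep("W", lead_wake_min * 2), rep(cycle, cycles),
    rep("W", trail_wake_min * 2))
}

.to_raw_stage <- function(stage) {
  lut <- c(W = "Sleep stage W", N1 = "Sleep stage 1", N2 = "Sleep stage 2",
           N3 = "Sleep stage 3", N4 = "Sleep stage 4", REM = "Sleep stage R",
           MOVEMENT = "Movement time", UNKNOWN = "Sleep stage ?")
  unname(lut[stage])
}

#' Synthesise a full-night recording
#'
#' Concatenates per-epoch synthetic EEG/EOG following a stage template and
#' builds the matching hypnogram (run-length encoded, Sleep-EDF style raw
#' stage strings) and the ground-truth eye-movement event log.
#'
#' @param subject_id,night identity of the recording.
#' @param template stage sequence, one label per epoch (short codes; `W`,
#'   `N1`..`N3`, `REM`, plus `MOVEMENT`/`UNKNOWN` which synthesise wake-like
#'   signal but are excluded downstream).
#' @param profiles list from [stage_profiles()].
#' @param fs sampling rate in Hz.
#' @param amp_scale overall amplitude factor (models inter-subject gain).
#' @param seed optional RNG seed.
#' @return list with `recording` (`psg_recording`), `hypnogram` (tibble
#'   `onset_s`, `duration_s`, `raw_stage`) and `events` (tibble with
#'   `epoch_index` and planted event columns).
#' @export
synth_recording <- function(subject_id = "S01", night = 1L,
                            template = make_stage_template(),
                            profiles = stage_profiles(), fs = 100,
                            amp_scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  epoch_s <- 30
  n <- length(template) * fs * epoch_s
  eeg <- numeric(n)
  eog <- numeric(n)
  events <- list()
  for (k in seq_along(template)) {
    st <- template[k]
    gen_st <- if (st %in% c("MOVEMENT", "UNKNOWN")) "W" else st
    prof <- profiles[[gen_st]]
    sel <- ((k - 1L) * fs * epoch_s + 1L):(k * fs * epoch_s)
    eeg[sel] <- amp_scale * synth_eeg_epoch(gen_st, prof, fs, epoch_s)
    eo <- synth_eog_epoch(gen_st, prof, fs, epoch_s)
    eog[sel] <- amp_scale * eo$signal
    if (nrow(eo$events) > 0L) {
      events[[length(events) + 1L]] <-
        dplyr::mutate(eo$events, epoch_index = k - 1L, .before = 1L,
                      p2p_uV = amp_scale * .data$p2p_uV)
    }
  }
  rle_t <- rle(template)
  ends <- cumsum(rle_t$lengths)
  hyp <- tibble::tibble(
    onset_s = (ends - rle_t$lengths) * epoch_s,
    duration_s = rle_t$lengths * epoch_s,
    raw_stage = .to_raw_stage(rle_t$values)
  )
  rec <- structure(
    list(eeg = eeg, eog = eog, fs = fs, subject_id = subject_id,
         night = as.integer(night)),
    class = "psg_recording"
  )
  ev <- if (length(events) > 0L) dplyr::bind_rows(events) else
    tibble::tibble(epoch_index = integer(0), start_s = numeric(0),
                   end_s = numeric(0), p2p_uV = numeric(0))
  list(recording = rec, hypnogram = hyp, events = ev)
}

#' Simulate a multi-subject polysomnography dataset
#'
#' Generates one synthetic night per subject (with a random per-subject
#' amplitude gain), segments it into labeled epochs and applies the
#' peripheral-wake trim. Optionally writes each night to EDF+ (signal file
#' plus hypnogram annotation file) under `dir`.
#'
#' @param n_subjects number of subjects.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param template stage sequence per night.
#' @param profiles generation profiles.
#' @param fs sampling rate in Hz.
#' @param trim apply [trim_wake_periphery()].
#' @param dir optional output directory for EDF+ files.
#' @return an [epoch_set()]; the ground-truth event log is attached as
#'   attribute `"events"` and per-subject gains as `"amp_scale"`.
#' @export
simulate_psg <- function(n_subjects = 5L, seed = 1L,
                         template = make_stage_template(),
                         profiles = stage_profiles(), fs = 100,
                         trim = TRUE, dir = NULL) {
  set.seed(seed)
  sets <- list()
  events <- list()
  gains <- stats::runif(n_subjects, 0.85, 1.15)
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    syn <- synth_recording(sid, night = 1L, template = template,
                           profiles = profiles, fs = fs,
                           amp_scale = gains[s])
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_edf_recording(file.path(dir, paste0(sid, "-PSG.edf")),
                          syn$recording$eeg, syn$recording$eog, fs,
                          patient_id = sid)
      write_hypnogram_edf(file.path(dir, paste0(sid, "-Hypnogram.edf")),
                          syn$hypnogram)
    }
    es <- segment_epochs(syn$recording, syn$hypnogram)
    if (trim) es <- trim_wake_periphery(es)
    sets[[s]] <- es
    events[[s]] <- dplyr::mutate(syn$events, subject_id = sid, .before = 1L)
  }
  out <- bind_epoch_sets(sets)
  attr(out, "events") <- dplyr::bind_rows(events)
  attr(out, "amp_scale") <- stats::setNames(gains, sprintf("S%02d", seq_len(n_subjects)))
  out
}
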