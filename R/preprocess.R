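# Kaiser-window FIR filterbank splitting the denoised EEG epoch into the
# seven classical rhythm bands.

#' Canonical EEG rhythm band table
#'
#' The seven bands used throughout the pipeline: Delta (0.5--4 Hz), Theta
#' (4--8), Alpha (8--12), Beta (13--35), Spindle (12--14), K-complex
#' (0.5--1.5) and Sawtooth (2--6). Bands deliberately overlap: a 3 Hz
#' component appears in both Delta and Sawtooth.
#'
#' @return tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "spindle", "kcomplex", "sawtooth"),
    lo   = c(0.5, 4, 8, 13, 12, 0.5, 2),
    hi   = c(4, 8, 12, 35, 14, 1.5, 6)
  )
}

#' Design a Kaiser-window FIR bandpass filter
#'
#' Linear-phase type-I FIR bandpass targeting 50 dB stopband attenuation,
#' with transition width `min(1 Hz, half the band width)`. Filter order from
#' the Kaiser formula; coefficients via a Kaiser-windowed ideal bandpass.
#'
#' @param lo,hi passband edges in Hz, `0 < lo < hi < fs/2`.
#' @param fs sampling rate in Hz.
#' @param atten_db target stopband attenuation in dB.
#' @param trans_hz transition width in Hz; default `min(1, (hi - lo) / 2)`.
#' @return numeric vector of filter coefficients (odd length, symmetric).
#' @export
design_bandpass <- function(lo, hi, fs, atten_db = 50, trans_hz = NULL) {
  if (!(lo > 0 && hi > lo)) stop("band edges must satisfy 0 < lo < hi", call. = FALSE)
  if (hi >= fs / 2) {
    stop("band upper edge ", hi, " Hz reaches or exceeds the Nyquist frequency ",
         fs / 2, " Hz", call. = FALSE)
  }
  if (is.null(trans_hz)) trans_hz <- min(1, (hi - lo) / 2)
  beta <- if (atten_db > 50) {
    0.1102 * (atten_db - 8.7)
  } else if (atten_db >= 21) {
    0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  } else 0
  d_omega <- 2 * pi * trans_hz / fs
  ord <- ceiling((atten_db - 7.95) / (2.285 * d_omega))
  if (ord %% 2L == 1L) ord <- ord + 1L  # even order -> odd, symmetric length
  w <- signal::kaiser(ord + 1L, beta)
  # ideal bandpass impulse response, cutoffs at the band edges
  m <- 0:ord
  centred <- m - ord / 2
  sinc <- function(fc, t) ifelse(t == 0, 2 * fc / fs, sin(2 * pi * fc * t / fs) / (pi * t))
  h <- (sinc(hi, centred) - sinc(lo, centred)) * w
  # normalise to unit gain at the passband centre
  f0 <- (lo + hi) / 2
  gain <- abs(sum(h * exp(-2i * pi * f0 / fs * m)))
  h / gain
}

# zero-phase FIR application: reflection padding absorbs edge transients and
# the linear-phase group delay (L-1)/2 is compensated exactly.
.apply_fir_zerophase <- function(x, h) {
  n <- length(x)
  L <- length(h)
  D <- (L - 1L) %/% 2L
  xp <- .reflect_pad(x, D, D)
  # FFT-based full convolution
  y <- stats::convolve(xp, rev(h), type = "open")
  y[(2L * D + 1L):(2L * D + n)]
}

#' Apply the rhythm-band filterbank to one epoch
#'
#' Filters a (denoised) epoch into each band of `bands` with zero-phase
#' Kaiser FIR filters. Outputs have the same length as the input.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param bands band table as from [eeg_bands()].
#' @param filters optional pre-designed coefficient list from
#'   [make_filterbank()]; designing once per recording is much faster.
#' @return named list of filtered signals, one per band.
#' @export
apply_filterbank <- function(x, fs, bands = eeg_bands(), filters = NULL) {
  if (is.null(filters)) filters <- make_filterbank(fs, bands)
  lapply(filters, function(h) .apply_fir_zerophase(x, h))
}

#' @rdname apply_filterbank
#' @export
make_filterbank <- function(fs, bands = eeg_bands()) {
  stats::setNames(
    purrr::map2(bands$lo, bands$hi, design_bandpass, fs = fs),
    bands$band
  )
}

#' Frequency response of an FIR filter
#'
#' @param h filter coefficients.
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return complex response at each frequency.
#' @keywords internal
fir_response <- function(h, f, fs) {
  m <- seq_along(h) - 1
  vapply(f, function(fi) sum(h * exp(-2i * pi * fi / fs * m)), complex(1))
}
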