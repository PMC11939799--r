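# Yule-Walker autoregressive spectral estimation and the band-power ratio
# features (absolute ratios, the four EEG relative ratios, and the two EOG
# eye-movement ratios).

#' Yule-Walker autoregressive power spectral density
#'
#' Fits an AR model of fixed order by the Yule-Walker (autocorrelation)
#' method and evaluates the one-sided parametric spectrum on a 0.1 Hz grid
#' over \[0, fs/2\]. The input is de-meaned internally.
#'
#' @param x numeric signal, longer than `order`.
#' @param fs sampling rate in Hz.
#' @param order AR model order (default 16).
#' @param df frequency grid step in Hz.
#' @return object of class `yw_psd`: list with `freqs` (Hz), `density`
#'   (power per Hz, non-negative), `ar_order`.
#' @export
yule_walker_psd <- function(x, fs, order = 16L, df = 0.1) {
  n <- length(x)
  if (n <= order) stop("signal must be longer than the AR order", call. = FALSE)
  x <- x - mean(x)
  if (.popvar(x) < .Machine$double.eps) {
    stop("zero-variance signal: autocorrelation matrix is singular", call. = FALSE)
  }
  fit <- stats::ar.yw(x, aic = FALSE, order.max = order, demean = FALSE)
  a <- fit$ar
  sigma2 <- fit$var.pred
  freqs <- seq(0, fs / 2, by = df)
  # one-sided AR spectrum: 2 sigma^2 / (fs |A(e^{-i omega})|^2)
  k <- seq_along(a)
  denom <- vapply(freqs, function(f) {
    Af <- 1 - sum(a * exp(-2i * pi * f / fs * k))
    Mod(Af)^2
  }, numeric(1))
  dens <- 2 * sigma2 / (fs * denom)
  structure(
    list(freqs = freqs, density = dens, ar_order = as.integer(order)),
    class = "yw_psd"
  )
}

#' @export
print.yw_psd <- function(x, ...) {
  cat("Yule-Walker PSD estimate (order ", x$ar_order, "), ",
      length(x$freqs), " frequencies in [", min(x$freqs), ", ",
      max(x$freqs), "] Hz\n", sep = "")
  invisible(x)
}

#' @export
tidy.yw_psd <- function(x, ...) {
  tibble::tibble(freq = x$freqs, density = x$density)
}

#' Band power from a PSD estimate
#'
#' Trapezoidal integral of the spectral density over \[lo, hi\].
#'
#' @param psd a `yw_psd` object.
#' @param lo,hi band edges in Hz, within the PSD grid.
#' @return scalar power.
#' @export
band_power <- function(psd, lo, hi) {
  if (hi <= lo) stop("inverted band: hi must exceed lo", call. = FALSE)
  if (lo < min(psd$freqs) || hi > max(psd$freqs)) {
    stop("band outside the PSD frequency grid", call. = FALSE)
  }
  sel <- psd$freqs >= lo - 1e-9 & psd$freqs <= hi + 1e-9
  f <- psd$freqs[sel]
  d <- psd$density[sel]
  sum(diff(f) * (d[-length(d)] + d[-1]) / 2)
}

#' Absolute band-power ratios
#'
#' Power in each of the seven canonical rhythm bands divided by the total
#' power, with total defined as the power over 0.5--35 Hz (the union of the
#' analysed bands). Each ratio lies in \[0, 1\].
#'
#' @param psd a `yw_psd` object for the EEG epoch.
#' @param bands band table as from [eeg_bands()].
#' @param total_band two-element numeric, the total-power range in Hz.
#' @return named numeric vector, `abs_<band>` for each band.
#' @export
absolute_band_power_ratios <- function(psd, bands = eeg_bands(),
                                       total_band = c(0.5, 35)) {
  total <- band_power(psd, total_band[1], total_band[2])
  if (total <= 0) stop("zero total power", call. = FALSE)
  r <- purrr::map2_dbl(bands$lo, bands$hi, function(lo, hi) {
    band_power(psd, lo, hi) / total
  })
  stats::setNames(r, paste0("abs_", bands$band))
}

#' Relative band-power ratios
#'
#' The four EEG power ratios between classical bands:
#' \deqn{F_{\delta/\theta} = P(0.5,4)/P(4,8),\quad
#'       F_{\theta/\alpha} = P(4,8)/P(8,12),}
#' \deqn{F_{\alpha/\beta} = P(8,12)/P(12,30),\quad
#'       F_{(\theta+\delta)/(\alpha+\beta)} = P(0.5,8)/P(8,30).}
#'
#' @param psd a `yw_psd` object for the EEG epoch.
#' @return named numeric vector `ratio_delta_theta`, `ratio_theta_alpha`,
#'   `ratio_alpha_beta`, `ratio_slow_fast`.
#' @export
relative_power_ratios <- function(psd) {
  p <- function(lo, hi) band_power(psd, lo, hi)
  den <- c(p(4, 8), p(8, 12), p(12, 30), p(8, 30))
  if (any(den <= 0)) stop("zero denominator band power", call. = FALSE)
  c(
    ratio_delta_theta = p(0.5, 4) / den[1],
    ratio_theta_alpha = p(4, 8) / den[2],
    ratio_alpha_beta  = p(8, 12) / den[3],
    ratio_slow_fast   = p(0.5, 8) / den[4]
  )
}

#' EOG eye-movement power ratios
#'
#' Slow (0.5--2 Hz) and rapid (2--5 Hz) eye-movement power, each relative to
#' the 0.5--30 Hz EOG power; separates the slow rolling eye movements of
#' drowsiness from the rapid saccadic activity of REM and wake.
#'
#' @param psd a `yw_psd` object for the EOG epoch.
#' @return named numeric vector `eog_slow_ratio`, `eog_rapid_ratio`.
#' @export
eog_power_ratios <- function(psd) {
  total <- band_power(psd, 0.5, 30)
  if (total <= 0) stop("zero EOG band power", call. = FALSE)
  c(
    eog_slow_ratio  = band_power(psd, 0.5, 2) / total,
    eog_rapid_ratio = band_power(psd, 2, 5) / total
  )
}
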