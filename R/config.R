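# Pipeline configuration: every tunable constant in one place, defaulting to
# the published operating point.

#' Pipeline configuration
#'
#' Bundles all tunable parameters of the staging pipeline. Defaults are the
#' published operating point: db4 wavelet, 7 decomposition levels, the
#' seven-band table of [eeg_bands()], 120 microvolt / 1.5 s eye-movement
#' thresholds with a 0.5 s exclusion pad, multiscale entropy with m = 2,
#' r = 0.2 SD at scales 9--13, AR order 16, Fisher prefilter threshold 0.1,
#' top-25 feature retention, and the tuned gradient-boosting parameters of
#' [model_params()].
#'
#' @param fs sampling rate in Hz.
#' @param bands rhythm band table (see [eeg_bands()]).
#' @param wavelet_levels wavelet decomposition depth.
#' @param wavelet_basis wavelet family.
#' @param lem_amp_uV,lem_dt_s eye-movement amplitude (microvolts) and
#'   extrema-interval (s) thresholds.
#' @param lem_pad_s guard interval removed around events (s).
#' @param lem_smooth_s smoothing window for extremum localisation (s).
#' @param mse_m,mse_r_factor,mse_scales,mse_cap multiscale entropy settings.
#' @param ar_order Yule-Walker AR order.
#' @param total_band total-power range (Hz) for absolute ratios.
#' @param fisher_threshold Fisher-score prefilter threshold.
#' @param top_k number of features kept after importance ranking.
#' @param model gradient-boosting parameters, see [model_params()].
#' @param eeg_only if `TRUE`, only the 65 EEG feature columns are extracted.
#' @return object of class `stager_config` (a named list); FIR filterbank
#'   coefficients are pre-designed and cached in `$filters`.
#' @export
stager_config <- function(fs = 100,
                          bands = eeg_bands(),
                          wavelet_levels = 7L,
                          wavelet_basis = "db4",
                          lem_amp_uV = 120,
                          lem_dt_s = 1.5,
                          lem_pad_s = 0.5,
                          lem_smooth_s = 0.5,
                          mse_m = 2L,
                          mse_r_factor = 0.2,
                          mse_scales = 9:13,
                          mse_cap = 3.0,
                          ar_order = 16L,
                          total_band = c(0.5, 35),
                          fisher_threshold = 0.1,
                          top_k = 25L,
                          model = model_params(),
                          eeg_only = FALSE) {
  cfg <- list(
    fs = fs, bands = bands,
    wavelet_levels = wavelet_levels, wavelet_basis = wavelet_basis,
    lem_amp_uV = lem_amp_uV, lem_dt_s = lem_dt_s,
    lem_pad_s = lem_pad_s, lem_smooth_s = lem_smooth_s,
    mse_m = mse_m, mse_r_factor = mse_r_factor,
    mse_scales = mse_scales, mse_cap = mse_cap,
    ar_order = ar_order, total_band = total_band,
    fisher_threshold = fisher_threshold, top_k = top_k,
    model = model, eeg_only = eeg_only,
    filters = make_filterbank(fs, bands)
  )
  structure(cfg, class = "stager_config")
}

#' @export
print.stager_config <- function(x, ...) {
  cat("Sleep staging configuration\n")
  cat("  fs ", x$fs, " Hz; wavelet ", x$wavelet_basis, " x", x$wavelet_levels,
      " levels; AR order ", x$ar_order, "\n", sep = "")
  cat("  LEM thresholds: ", x$lem_amp_uV, " uV / ", x$lem_dt_s, " s; pad ",
      x$lem_pad_s, " s\n", sep = "")
  cat("  MSE: m = ", x$mse_m, ", r = ", x$mse_r_factor, " SD, scales ",
      paste(x$mse_scales, collapse = ","), "\n", sep = "")
  cat("  selection: Fisher >= ", x$fisher_threshold, ", top ", x$top_k,
      "; features: ", if (x$eeg_only) "EEG only (65)" else "EEG + EOG (76)",
      "\n", sep = "")
  invisible(x)
}
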