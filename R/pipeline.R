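# Assembly of the canonical 76-column feature matrix.

.TIME_FEATURES <- c("range", "mean", "variance", "std",
                    "peak_count", "zero_crossings", "diff_variance")

#' Canonical feature inventory
#'
#' The fixed column order of the feature matrix: 49 EEG time-domain features
#' (7 statistics per rhythm band, band-major), 7 absolute band-power ratios,
#' 4 relative power ratios, 5 multiscale entropies (scales 9--13), then the
#' 11 EOG features (7 broadband time-domain statistics, the eye-movement
#' count and the eye-movement-excluded difference variance, and the
#' slow/rapid eye-movement power ratios) -- 76 columns in all, or the 65 EEG
#' columns in EEG-only mode.
#'
#' @param eeg_only drop the 11 EOG columns.
#' @param bands rhythm band table.
#' @param mse_scales multiscale entropy scales.
#' @return tibble with columns `index` (0-based), `name`, `channel`,
#'   `family`, `band`.
#' @export
feature_spec <- function(eeg_only = FALSE, bands = eeg_bands(),
                         mse_scales = 9:13) {
  eeg_time <- tidyr::expand_grid(band = bands$band, stat = .TIME_FEATURES) |>
    dplyr::mutate(
      name = paste("eeg", .data$band, .data$stat, sep = "_"),
      channel = "EEG", family = "time"
    ) |>
    dplyr::select("name", "channel", "family", "band")
  eeg_abs <- tibble::tibble(
    name = paste0("eeg_abs_", bands$band),
    channel = "EEG", family = "psd", band = bands$band
  )
  eeg_rel <- tibble::tibble(
    name = c("eeg_ratio_delta_theta", "eeg_ratio_theta_alpha",
             "eeg_ratio_alpha_beta", "eeg_ratio_slow_fast"),
    channel = "EEG", family = "psd", band = NA_character_
  )
  eeg_mse <- tibble::tibble(
    name = paste0("eeg_mse_", mse_scales),
    channel = "EEG", family = "mse", band = NA_character_
  )
  spec <- dplyr::bind_rows(eeg_time, eeg_abs, eeg_rel, eeg_mse)
  if (!eeg_only) {
    eog_time <- tibble::tibble(
      name = paste0("eog_", .TIME_FEATURES),
      channel = "EOG", family = "time", band = NA_character_
    )
    eog_novel <- tibble::tibble(
      name = c("eog_lem_count", "eog_diff_variance_ex_lem"),
      channel = "EOG", family = "time", band = NA_character_
    )
    eog_psd <- tibble::tibble(
      name = c("eog_slow_ratio", "eog_rapid_ratio"),
      channel = "EOG", family = "psd", band = NA_character_
    )
    spec <- dplyr::bind_rows(spec, eog_time, eog_novel, eog_psd)
  }
  dplyr::mutate(spec, index = dplyr::row_number() - 1L, .before = 1L)
}

#' Extract the feature vector of a single epoch
#'
#' Denoises both channels, applies the rhythm filterbank to the EEG, and
#' computes all features of [feature_spec()] in canonical order.
#'
#' @param eeg_epoch,eog_epoch numeric signals (microvolts), one 30 s epoch.
#' @param config a [stager_config()].
#' @return named numeric vector (length 76, or 65 in EEG-only mode). Values
#'   may be non-finite for degenerate epochs; [build_feature_matrix()] drops
#'   such rows.
#' @export
extract_epoch_features <- function(eeg_epoch, eog_epoch = NULL,
                                   config = stager_config()) {
  fs <- config$fs
  eeg <- wavelet_denoise(eeg_epoch, levels = config$wavelet_levels,
                         basis = config$wavelet_basis)

  bands <- apply_filterbank(eeg, fs, config$bands, filters = config$filters)
  eeg_time <- unlist(lapply(config$bands$band, function(b) {
    v <- as.numeric(time_domain_features(bands[[b]])[1, ])
    stats::setNames(v, paste("eeg", b, .TIME_FEATURES, sep = "_"))
  }))

  psd <- yule_walker_psd(eeg, fs, order = config$ar_order)
  abs_r <- absolute_band_power_ratios(psd, config$bands, config$total_band)
  names(abs_r) <- paste0("eeg_", names(abs_r))
  rel_r <- relative_power_ratios(psd)
  names(rel_r) <- paste0("eeg_", names(rel_r))
  mse <- multiscale_entropy(eeg, m = config$mse_m,
                            r_factor = config$mse_r_factor,
                            scales = config$mse_scales, cap = config$mse_cap)
  names(mse) <- paste0("eeg_", names(mse))

  out <- c(eeg_time, abs_r, rel_r, mse)
  if (!config$eeg_only) {
    if (is.null(eog_epoch)) stop("EOG epoch required unless eeg_only", call. = FALSE)
    eog <- wavelet_denoise(eog_epoch, levels = config$wavelet_levels,
                           basis = config$wavelet_basis)
    eog_time <- stats::setNames(as.numeric(time_domain_features(eog)[1, ]),
                                paste0("eog_", .TIME_FEATURES))
    ev <- detect_large_eye_movements(eog, fs, amp_uV = config$lem_amp_uV,
                                     dt_s = config$lem_dt_s,
                                     smooth_s = config$lem_smooth_s)
    dv_ex <- suppressWarnings(
      diff_variance_excluding_lem(eog, fs, ev, pad_s = config$lem_pad_s)
    )
    eog_psd <- yule_walker_psd(eog, fs, order = config$ar_order)
    out <- c(out, eog_time,
             c(eog_lem_count = nrow(ev), eog_diff_variance_ex_lem = dv_ex),
             eog_power_ratios(eog_psd))
  }
  out
}

#' Build the feature matrix of an epoch set
#'
#' One row per retained epoch, metadata columns first. Epochs whose feature
#' vector contains a non-finite value (e.g. a degenerate flat signal) are
#' dropped with a message. Deterministic given the input and configuration.
#'
#' @param epochs an [epoch_set()].
#' @param config a [stager_config()].
#' @return tibble with `subject_id`, `night`, `epoch_index`, `stage`
#'   followed by the feature columns of [feature_spec()].
#' @export
build_feature_matrix <- function(epochs, config = stager_config()) {
  n <- nrow(epochs$meta)
  if (n == 0L) stop("empty epoch set", call. = FALSE)
  spec <- feature_spec(config$eeg_only, config$bands, config$mse_scales)
  vals <- matrix(NA_real_, n, nrow(spec),
                 dimnames = list(NULL, spec$name))
  for (i in seq_len(n)) {
    v <- tryCatch(
      extract_epoch_features(epochs$eeg[i, ],
                             if (config$eeg_only) NULL else epochs$eog[i, ],
                             config),
      error = function(e) rep(NA_real_, nrow(spec))
    )
    vals[i, ] <- as.numeric(v)
  }
  ok <- apply(is.finite(vals), 1L, all)
  if (any(!ok)) {
    message(sum(!ok), " epoch(s) dropped for non-finite features")
  }
  dplyr::bind_cols(
    epochs$meta[ok, , drop = FALSE],
    tibble::as_tibble(vals[ok, , drop = FALSE])
  )
}

#' Names of the feature columns in a feature tibble
#'
#' @param features a feature tibble from [build_feature_matrix()].
#' @return character vector of feature column names (metadata excluded).
#' @export
feature_names <- function(features) {
  setdiff(names(features), c("subject_id", "night", "epoch_index", "stage"))
}
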