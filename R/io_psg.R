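# Label harmonisation, epoch segmentation and peripheral-wake trimming.

#' Sleep stage alphabet
#'
#' The five-class staging alphabet in canonical order.
#' @return character vector `c("W", "N1", "N2", "N3", "REM")`.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

#' Harmonise a raw hypnogram stage string
#'
#' Maps R&K annotation strings to the five-class alphabet: stages 3 and 4
#' are merged into N3 (deep sleep), and movement-time / unscored epochs map
#' to `"EXCLUDED"` so they can be dropped during segmentation.
#'
#' @param raw_stage character vector of annotation strings (e.g.
#'   `"Sleep stage W"`, `"Sleep stage 4"`, `"Movement time"`); the short
#'   forms `W`, `N1`..`N4`, `REM` are also accepted.
#' @return character vector over `{W, N1, N2, N3, REM, EXCLUDED}`.
#' @export
map_stage_label <- function(raw_stage) {
  lut <- c(
    "Sleep stage W" = "W",
    "Sleep stage 1" = "N1",
    "Sleep stage 2" = "N2",
    "Sleep stage 3" = "N3",
    "Sleep stage 4" = "N3",
    "Sleep stage R" = "REM",
    "Sleep stage ?" = "EXCLUDED",
    "Movement time" = "EXCLUDED",
    "W" = "W", "N1" = "N1", "N2" = "N2", "N3" = "N3", "N4" = "N3",
    "REM" = "REM", "R" = "REM", "MOVEMENT" = "EXCLUDED", "UNKNOWN" = "EXCLUDED"
  )
  out <- unname(lut[raw_stage])
  if (anyNA(out)) {
    bad <- unique(raw_stage[is.na(out)])
    stop("unrecognised stage string(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct a labeled epoch set
#'
#' Container pairing aligned EEG/EOG epoch matrices (one row per 30 s epoch)
#' with stage labels and subject identity.
#'
#' @param eeg,eog numeric matrices, `n_epochs x (epoch_s * fs)` samples.
#' @param meta tibble with columns `subject_id`, `night`, `epoch_index`,
#'   `stage` (one row per epoch).
#' @param fs sampling rate in Hz.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(eeg, eog, meta, fs) {
  stopifnot(nrow(eeg) == nrow(eog), nrow(eeg) == nrow(meta))
  bad <- setdiff(unique(meta$stage), stage_levels())
  if (length(bad) > 0L) {
    stop("labels outside the staging alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(eeg = eeg, eog = eog, meta = tibble::as_tibble(meta), fs = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("Labeled epoch set: ", nrow(x$meta), " epochs x ", ncol(x$eeg),
      " samples (", x$fs, " Hz), ",
      dplyr::n_distinct(x$meta$subject_id), " subject(s)\n", sep = "")
  print(table(factor(x$meta$stage, levels = stage_levels())))
  invisible(x)
}

#' Segment a recording into labeled 30-second epochs
#'
#' Cuts the recording into half-open windows `[k*epoch_s, (k+1)*epoch_s)`
#' labeled from the hypnogram. Epochs labeled MOVEMENT/UNKNOWN (mapped to
#' `EXCLUDED`), epochs containing non-finite samples, and trailing partial
#' windows are dropped.
#'
#' @param rec a `psg_recording` (see [read_edf_recording()]).
#' @param hypnogram tibble with `onset_s`, `duration_s`, `raw_stage`.
#' @param epoch_s epoch length in seconds.
#' @return an [epoch_set()].
#' @export
segment_epochs <- function(rec, hypnogram, epoch_s = 30) {
  fs <- rec$fs
  spe <- fs * epoch_s
  if (spe != round(spe)) stop("fs * epoch_s must be an integer", call. = FALSE)
  spe <- as.integer(spe)
  n_sig_epochs <- length(rec$eeg) %/% spe

  if (nrow(hypnogram) == 0L) {
    return(epoch_set(
      matrix(numeric(0), 0, spe), matrix(numeric(0), 0, spe),
      tibble::tibble(subject_id = character(0), night = integer(0),
                     epoch_index = integer(0), stage = character(0)),
      fs
    ))
  }
  if (any(hypnogram$duration_s %% epoch_s != 0)) {
    stop("hypnogram durations must be multiples of the epoch length", call. = FALSE)
  }
  hyp_end <- max(hypnogram$onset_s + hypnogram$duration_s)
  if (hyp_end > n_sig_epochs * epoch_s + 1e-9) {
    stop("hypnogram extends beyond the recorded signal", call. = FALSE)
  }

  # expand hypnogram to one label per epoch index
  labels <- rep(NA_character_, n_sig_epochs)
  for (i in seq_len(nrow(hypnogram))) {
    k0 <- hypnogram$onset_s[i] / epoch_s
    nk <- hypnogram$duration_s[i] / epoch_s
    labels[(k0 + 1):(k0 + nk)] <- map_stage_label(hypnogram$raw_stage[i])
  }
  covered <- which(!is.na(labels) & labels != "EXCLUDED")

  rows <- length(covered)
  eeg <- matrix(NA_real_, rows, spe)
  eog <- matrix(NA_real_, rows, spe)
  for (r in seq_len(rows)) {
    k <- covered[r]
    sel <- ((k - 1L) * spe + 1L):(k * spe)
    eeg[r, ] <- rec$eeg[sel]
    eog[r, ] <- rec$eog[sel]
  }
  finite <- apply(is.finite(eeg), 1L, all) & apply(is.finite(eog), 1L, all)
  if (any(!finite)) {
    message(sum(!finite), " epoch(s) dropped for non-finite samples")
  }
  keep <- which(finite)
  epoch_set(
    eeg[keep, , drop = FALSE], eog[keep, , drop = FALSE],
    tibble::tibble(
      subject_id = rec$subject_id, night = rec$night,
      epoch_index = covered[keep] - 1L, stage = labels[covered[keep]]
    ),
    fs
  )
}

#' Trim peripheral wake beyond a 30-minute margin
#'
#' Sleep-lab recordings start and end with long wake periods; only
#' `margin_s` seconds (default 30 min = 60 epochs) of wake before the first
#' and after the last sleep epoch are kept. Interior wake is untouched.
#' Applied per subject-night.
#'
#' @param epochs an [epoch_set()], temporally ordered within each
#'   subject-night.
#' @param margin_s wake margin retained on each side, in seconds.
#' @param epoch_s epoch length in seconds.
#' @return trimmed [epoch_set()].
#' @export
trim_wake_periphery <- function(epochs, margin_s = 1800, epoch_s = 30) {
  margin <- margin_s %/% epoch_s
  meta <- epochs$meta
  grp <- paste(meta$subject_id, meta$night, sep = "\r")
  keep <- logical(nrow(meta))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    st <- meta$stage[rows]
    sleep <- which(st != "W")
    if (length(sleep) == 0L) {
      warning("all-wake recording for ", sub("\r", " night ", g),
              "; nothing trimmed", call. = FALSE)
      keep[rows] <- TRUE
      next
    }
    lo <- max(1L, min(sleep) - margin)
    hi <- min(length(rows), max(sleep) + margin)
    keep[rows[lo:hi]] <- TRUE
  }
  epoch_set(
    epochs$eeg[keep, , drop = FALSE], epochs$eog[keep, , drop = FALSE],
    meta[keep, , drop = FALSE], epochs$fs
  )
}

#' Row-bind epoch sets
#'
#' @param ... `epoch_set` objects with identical sampling rates and widths.
#' @return combined `epoch_set`.
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "epoch_set")) {
    sets <- sets[[1]]
  }
  fs <- unique(vapply(sets, function(s) s$fs, numeric(1)))
  stopifnot(length(fs) == 1L)
  epoch_set(
    do.call(rbind, lapply(sets, function(s) s$eeg)),
    do.call(rbind, lapply(sets, function(s) s$eog)),
    dplyr::bind_rows(lapply(sets, function(s) s$meta)),
    fs
  )
}
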