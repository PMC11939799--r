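# Minimal EDF/EDF+ input/output: 16-bit signal records plus the EDF+
# timestamped-annotation (TAL) encoding used by hypnogram files. Covers
# exactly what the staging pipeline needs: two 100 Hz channels in microvolts
# and a stage-annotation list.

.pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.read_field <- function(con, width) trimws(readChar(con, width, useBytes = TRUE))

#' Write a two-channel recording to EDF
#'
#' Writes EEG and EOG signals as 16-bit EDF with one-second data records and
#' physical dimension microvolts. Amplitudes are quantised to the 16-bit
#' digital range scaled to the per-channel absolute maximum.
#'
#' @param path output file path.
#' @param eeg,eog numeric signals in microvolts, equal length.
#' @param fs sampling rate in Hz (samples per record).
#' @param eeg_label,eog_label channel labels written to the header.
#' @param patient_id free-text patient identification field.
#' @return `path`, invisibly.
#' @export
write_edf_recording <- function(path, eeg, eog, fs,
                                eeg_label = "EEG Fpz-Cz",
                                eog_label = "EOG horizontal",
                                patient_id = "X") {
  stopifnot(length(eeg) == length(eog))
  n_rec <- length(eeg) %/% fs
  eeg <- eeg[seq_len(n_rec * fs)]
  eog <- eog[seq_len(n_rec * fs)]
  ns <- 2L

  phys_max <- vapply(list(eeg, eog), function(s) max(1, ceiling(max(abs(s)))), numeric(1))
  dig_max <- 32767L
  dig_min <- -32768L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.pad_field("0", 8), con, eos = NULL)
  writeChar(.pad_field(patient_id, 80), con, eos = NULL)
  writeChar(.pad_field("Startdate 01-JAN-2000", 80), con, eos = NULL)
  writeChar(.pad_field("01.01.00", 8), con, eos = NULL)
  writeChar(.pad_field("00.00.00", 8), con, eos = NULL)
  writeChar(.pad_field(256L * (1L + ns), 8), con, eos = NULL)
  writeChar(.pad_field("EDF+C", 44), con, eos = NULL)
  writeChar(.pad_field(n_rec, 8), con, eos = NULL)
  writeChar(.pad_field(1, 8), con, eos = NULL)
  writeChar(.pad_field(ns, 4), con, eos = NULL)

  labels <- c(eeg_label, eog_label)
  for (l in labels) writeChar(.pad_field(l, 16), con, eos = NULL)
  for (i in 1:ns) writeChar(.pad_field("", 80), con, eos = NULL)
  for (i in 1:ns) writeChar(.pad_field("uV", 8), con, eos = NULL)
  for (i in 1:ns) writeChar(.pad_field(-phys_max[i], 8), con, eos = NULL)
  for (i in 1:ns) writeChar(.pad_field(phys_max[i], 8), con, eos = NULL)
  for (i in 1:ns) writeChar(.pad_field(dig_min, 8), con, eos = NULL)
  for (i in 1:ns) writeChar(.pad_field(dig_max, 8), con, eos = NULL)
  for (i in 1:ns) writeChar(.pad_field("", 80), con, eos = NULL)
  for (i in 1:ns) writeChar(.pad_field(fs, 8), con, eos = NULL)
  for (i in 1:ns) writeChar(.pad_field("", 32), con, eos = NULL)

  to_dig <- function(s, pmax) {
    d <- round((s + pmax) / (2 * pmax) * (dig_max - dig_min) + dig_min)
    as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  dig <- list(to_dig(eeg, phys_max[1]), to_dig(eog, phys_max[2]))
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(dig[[1]][sel], con, size = 2L, endian = "little")
    writeBin(dig[[2]][sel], con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_edf_header <- function(con) {
  version <- .read_field(con, 8)
  if (!nzchar(version)) stop("unreadable EDF header", call. = FALSE)
  patient <- .read_field(con, 80)
  recording <- .read_field(con, 80)
  startdate <- .read_field(con, 8)
  starttime <- .read_field(con, 8)
  header_bytes <- as.integer(.read_field(con, 8))
  reserved <- .read_field(con, 44)
  n_rec <- as.integer(.read_field(con, 8))
  rec_dur <- as.numeric(.read_field(con, 8))
  ns <- as.integer(.read_field(con, 4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header: bad signal count", call. = FALSE)
  fld <- function(width) vapply(seq_len(ns), function(i) .read_field(con, width), character(1))
  list(
    patient = patient, recording = recording, reserved = reserved,
    n_rec = n_rec, rec_dur = rec_dur, ns = ns, header_bytes = header_bytes,
    labels = fld(16), transducer = fld(80), phys_dim = fld(8),
    phys_min = as.numeric(fld(8)), phys_max = as.numeric(fld(8)),
    dig_min = as.numeric(fld(8)), dig_max = as.numeric(fld(8)),
    prefilter = fld(80), spr = as.integer(fld(8)), sig_reserved = fld(32)
  )
}

#' Read a two-channel recording from an EDF/EDF+ file
#'
#' @param path EDF file path.
#' @param eeg_channel,eog_channel channel labels to extract (exact match
#'   after whitespace trimming).
#' @param subject_id,night identity attached to the returned recording.
#' @return object of class `psg_recording`: list with numeric `eeg`, `eog`
#'   (microvolts), `fs`, `subject_id`, `night`.
#' @export
read_edf_recording <- function(path, eeg_channel = "EEG Fpz-Cz",
                               eog_channel = "EOG horizontal",
                               subject_id = basename(path), night = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .read_edf_header(con)

  pick <- function(lbl) {
    i <- which(hdr$labels == lbl)
    if (length(i) != 1L) {
      stop("channel '", lbl, "' not found; available: ",
           paste(hdr$labels, collapse = ", "), call. = FALSE)
    }
    i
  }
  ie <- pick(eeg_channel)
  io <- pick(eog_channel)

  raw_sig <- lapply(seq_len(hdr$ns), function(i) {
    if (i %in% c(ie, io)) numeric(hdr$n_rec * hdr$spr[i]) else NULL
  })
  for (r in seq_len(hdr$n_rec)) {
    for (i in seq_len(hdr$ns)) {
      v <- readBin(con, integer(), n = hdr$spr[i], size = 2L, endian = "little")
      if (i %in% c(ie, io)) {
        raw_sig[[i]][((r - 1L) * hdr$spr[i] + 1L):(r * hdr$spr[i])] <- v
      }
    }
  }
  to_phys <- function(i) {
    scale <- (hdr$phys_max[i] - hdr$phys_min[i]) / (hdr$dig_max[i] - hdr$dig_min[i])
    (raw_sig[[i]] - hdr$dig_min[i]) * scale + hdr$phys_min[i]
  }
  fs_e <- hdr$spr[ie] / hdr$rec_dur
  fs_o <- hdr$spr[io] / hdr$rec_dur
  if (fs_e != fs_o) stop("EEG and EOG sampling rates differ", call. = FALSE)
  structure(
    list(eeg = to_phys(ie), eog = to_phys(io), fs = fs_e,
         subject_id = subject_id, night = as.integer(night)),
    class = "psg_recording"
  )
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("PSG recording: subject ", x$subject_id, ", night ", x$night, ", ",
      length(x$eeg), " samples at ", x$fs, " Hz (",
      round(length(x$eeg) / x$fs / 3600, 2), " h)\n", sep = "")
  invisible(x)
}

#' Write a hypnogram as an EDF+ annotation file
#'
#' Encodes stage annotations as EDF+ timestamped annotation lists (TALs) in
#' a single annotation-only data record, mirroring the layout of Sleep-EDF
#' hypnogram files.
#'
#' @param path output file path.
#' @param hypnogram tibble/data frame with `onset_s`, `duration_s`,
#'   `raw_stage` columns.
#' @return `path`, invisibly.
#' @export
write_hypnogram_edf <- function(path, hypnogram) {
  D14 <- rawToChar(as.raw(0x14))  # annotation delimiter
  D15 <- rawToChar(as.raw(0x15))  # onset/duration delimiter
  NUL <- as.raw(0L)               # TAL terminator
  tals <- c(
    paste0("+0", D14, D14),
    vapply(seq_len(nrow(hypnogram)), function(i) {
      sprintf("+%g%s%g%s%s%s",
              hypnogram$onset_s[i], D15, hypnogram$duration_s[i], D14,
              hypnogram$raw_stage[i], D14)
    }, character(1))
  )
  payload <- unlist(lapply(tals, function(t) c(charToRaw(t), NUL)))
  if (length(payload) %% 2L == 1L) payload <- c(payload, NUL)
  spr <- length(payload) %/% 2L
  total_dur <- max(hypnogram$onset_s + hypnogram$duration_s, 0)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.pad_field("0", 8), con, eos = NULL)
  writeChar(.pad_field("X", 80), con, eos = NULL)
  writeChar(.pad_field("Startdate 01-JAN-2000", 80), con, eos = NULL)
  writeChar(.pad_field("01.01.00", 8), con, eos = NULL)
  writeChar(.pad_field("00.00.00", 8), con, eos = NULL)
  writeChar(.pad_field(256L * 2L, 8), con, eos = NULL)
  writeChar(.pad_field("EDF+C", 44), con, eos = NULL)
  writeChar(.pad_field(1L, 8), con, eos = NULL)
  writeChar(.pad_field(total_dur, 8), con, eos = NULL)
  writeChar(.pad_field(1L, 4), con, eos = NULL)
  writeChar(.pad_field("EDF Annotations", 16), con, eos = NULL)
  writeChar(.pad_field("", 80), con, eos = NULL)
  writeChar(.pad_field("", 8), con, eos = NULL)
  writeChar(.pad_field(-1, 8), con, eos = NULL)
  writeChar(.pad_field(1, 8), con, eos = NULL)
  writeChar(.pad_field(-32768L, 8), con, eos = NULL)
  writeChar(.pad_field(32767L, 8), con, eos = NULL)
  writeChar(.pad_field("", 80), con, eos = NULL)
  writeChar(.pad_field(spr, 8), con, eos = NULL)
  writeChar(.pad_field("", 32), con, eos = NULL)
  writeBin(payload, con)
  invisible(path)
}

.parse_tals <- function(raw_bytes) {
  D14 <- rawToChar(as.raw(0x14))
  D15 <- rawToChar(as.raw(0x15))
  # split on NUL terminators at the byte level
  is_nul <- raw_bytes == as.raw(0L)
  grp <- cumsum(is_nul)
  chunks <- split(raw_bytes[!is_nul], grp[!is_nul])
  chunks <- vapply(chunks, rawToChar, character(1))
  chunks <- chunks[nzchar(chunks)]
  out <- list()
  for (ch in chunks) {
    parts <- strsplit(ch, D14, fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    head <- parts[1]
    texts <- parts[-1]
    texts <- texts[nzchar(texts)]
    if (length(texts) == 0L) next
    od <- strsplit(head, D15, fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(od[1]))
    dur <- if (length(od) > 1L) suppressWarnings(as.numeric(od[2])) else NA_real_
    if (is.na(onset)) next
    for (tx in texts) {
      out[[length(out) + 1L]] <- tibble::tibble(
        onset_s = onset, duration_s = dur, raw_stage = tx
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(onset_s = numeric(0), duration_s = numeric(0),
                          raw_stage = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Read a hypnogram (EDF+ annotations or CSV)
#'
#' Accepts either an EDF+ annotation file (as written by
#' [write_hypnogram_edf()] or as distributed alongside Sleep-EDF PSGs) or a
#' plain CSV with columns `onset_s`, `duration_s`, `stage`.
#'
#' @param path hypnogram file path; format chosen by extension (`.csv` vs
#'   anything else treated as EDF+).
#' @return tibble with `onset_s`, `duration_s`, `raw_stage`.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("onset_s", "duration_s", "stage")
    if (!all(need %in% names(df))) {
      stop("CSV hypnogram must have columns onset_s, duration_s, stage", call. = FALSE)
    }
    return(tibble::tibble(
      onset_s = as.numeric(df$onset_s),
      duration_s = as.numeric(df$duration_s),
      raw_stage = as.character(df$stage)
    ))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .read_edf_header(con)
  ann_idx <- which(hdr$labels == "EDF Annotations")
  if (length(ann_idx) == 0L) stop("no 'EDF Annotations' signal in file", call. = FALSE)
  payload <- raw(0)
  for (r in seq_len(hdr$n_rec)) {
    for (i in seq_len(hdr$ns)) {
      b <- readBin(con, raw(), n = 2L * hdr$spr[i])
      if (i %in% ann_idx) payload <- c(payload, b)
    }
  }
  tal <- .parse_tals(payload)
  tal[!is.na(tal$duration_s) & tal$duration_s > 0, , drop = FALSE]
}
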