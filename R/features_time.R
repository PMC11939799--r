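# Time-domain features, large-eye-movement (LEM) detection on the EOG, and
# the LEM-excluded difference variance.

.popvar <- function(x) {
  if (length(x) == 0L) return(0)
  mean((x - mean(x))^2)
}

#' Seven time-domain features of a signal
#'
#' Range (max - min), mean, population variance (1/N), standard deviation,
#' strict-local-maximum peak count, zero-crossing count (sign-product rule on
#' consecutive non-zero samples, so touching zero without crossing does not
#' count), and the variance of the first-difference sequence.
#'
#' @param x numeric signal, length at least 3.
#' @return one-row tibble with columns `range`, `mean`, `variance`, `std`,
#'   `peak_count`, `zero_crossings`, `diff_variance`.
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  if (n < 3L) stop("signal too short for time-domain features", call. = FALSE)
  v <- .popvar(x)
  mid <- x[2:(n - 1L)]
  peaks <- sum(mid > x[1:(n - 2L)] & mid > x[3:n])
  nz <- x[x != 0]
  zc <- if (length(nz) >= 2L) sum(nz[-length(nz)] * nz[-1] < 0) else 0L
  tibble::tibble(
    range = max(x) - min(x),
    mean = mean(x),
    variance = v,
    std = sqrt(v),
    peak_count = peaks,
    zero_crossings = zc,
    diff_variance = difference_variance(x)
  )
}

#' Difference variance
#'
#' Population variance (1/N) of the first-order difference sequence
#' \eqn{D_n = X_n - X_{n-1}}; a smoothness measure -- smaller values mean a
#' smoother signal.
#'
#' @param x numeric signal, length at least 2.
#' @return scalar.
#' @export
difference_variance <- function(x) {
  if (length(x) < 2L) stop("signal too short for a difference sequence", call. = FALSE)
  .popvar(diff(x))
}

# strict local extrema of a vector; returns indices and type (+1 max / -1 min)
.local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(idx = integer(0), type = integer(0)))
  mid <- x[2:(n - 1L)]
  is_max <- mid > x[1:(n - 2L)] & mid > x[3:n]
  is_min <- mid < x[1:(n - 2L)] & mid < x[3:n]
  idx <- which(is_max | is_min) + 1L
  type <- ifelse(is_max[idx - 1L], 1L, -1L)
  list(idx = idx, type = type)
}

#' Detect large eye movements in an EOG epoch
#'
#' A large eye movement (LEM) is a biphasic EOG deflection whose adjacent
#' local maximum/minimum pair is separated by at most `dt_s` seconds with a
#' peak-to-peak amplitude above `amp_uV` microvolts. Extrema are localised on
#' a moving-average smoothed copy of the signal (window `smooth_s`, used for
#' localisation only) then refined to the raw extremum nearby; consecutive
#' same-type extrema are collapsed to the more extreme one, and runs of
#' overlapping qualifying pairs are merged into a single event spanning their
#' union (`duration_s` records the largest single extrema interval in the
#' run, `p2p_uV` the largest pair amplitude).
#'
#' @param eog numeric EOG signal in microvolts (ideally denoised).
#' @param fs sampling rate in Hz.
#' @param amp_uV peak-to-peak amplitude threshold in microvolts.
#' @param dt_s maximum time between the extrema of a pair, in seconds.
#' @param smooth_s moving-average window (s) for extremum localisation.
#' @return tibble with columns `start_idx`, `end_idx`, `p2p_uV`,
#'   `duration_s`; zero rows when no event qualifies.
#' @export
detect_large_eye_movements <- function(eog, fs, amp_uV = 120, dt_s = 1.5,
                                       smooth_s = 0.5) {
  empty <- tibble::tibble(
    start_idx = integer(0), end_idx = integer(0),
    p2p_uV = numeric(0), duration_s = numeric(0)
  )
  n <- length(eog)
  if (n < 3L) return(empty)

  w <- max(1L, min(round(smooth_s * fs), n %/% 2L))
  sm <- if (w > 1L) as.numeric(stats::filter(eog, rep(1 / w, w), sides = 2)) else eog
  sm[is.na(sm)] <- eog[is.na(sm)]

  ex <- .local_extrema(sm)
  if (length(ex$idx) < 2L) return(empty)

  # refine each extremum to the raw-signal extremum within +/- w/2 samples
  half <- max(1L, w %/% 2L)
  refined <- vapply(seq_along(ex$idx), function(i) {
    lo <- max(1L, ex$idx[i] - half)
    hi <- min(n, ex$idx[i] + half)
    win <- lo:hi
    if (ex$type[i] > 0L) win[which.max(eog[win])] else win[which.min(eog[win])]
  }, integer(1))

  # collapse consecutive same-type extrema to the more extreme one
  keep_idx <- integer(0)
  keep_type <- integer(0)
  for (i in seq_along(refined)) {
    if (length(keep_type) > 0L && ex$type[i] == keep_type[length(keep_type)]) {
      j <- length(keep_idx)
      better <- if (ex$type[i] > 0L) eog[refined[i]] > eog[keep_idx[j]]
                else eog[refined[i]] < eog[keep_idx[j]]
      if (better) keep_idx[j] <- refined[i]
    } else {
      keep_idx <- c(keep_idx, refined[i])
      keep_type <- c(keep_type, ex$type[i])
    }
  }
  if (length(keep_idx) < 2L) return(empty)

  i1 <- keep_idx[-length(keep_idx)]
  i2 <- keep_idx[-1]
  p2p <- abs(eog[i2] - eog[i1])
  dt <- (i2 - i1) / fs
  qual <- which(p2p > amp_uV & dt <= dt_s)
  if (length(qual) == 0L) return(empty)

  # merge runs of consecutive qualifying pairs (they share an extremum)
  runs <- split(qual, cumsum(c(1L, diff(qual) != 1L)))
  purrr::map_dfr(runs, function(r) {
    tibble::tibble(
      start_idx = i1[r[1]],
      end_idx = i2[r[length(r)]],
      p2p_uV = max(p2p[r]),
      duration_s = max(dt[r])
    )
  })
}

#' Difference variance excluding large eye movements
#'
#' Removes each detected event span plus `pad_s` seconds on either side from
#' the EOG signal, then pools the first differences of the remaining
#' contiguous segments (differences never span a cut) and returns their
#' population variance. Quantifies the background smoothness of the EOG once
#' large deflections are discounted.
#'
#' @param eog numeric EOG signal.
#' @param fs sampling rate in Hz.
#' @param events tibble from [detect_large_eye_movements()] on the same signal.
#' @param pad_s guard interval removed around each event, in seconds.
#' @return scalar; 0 (with a warning) if no samples survive.
#' @export
diff_variance_excluding_lem <- function(eog, fs, events, pad_s = 0.5) {
  n <- length(eog)
  keep <- rep(TRUE, n)
  if (nrow(events) > 0L) {
    pad <- round(pad_s * fs)
    for (i in seq_len(nrow(events))) {
      lo <- max(1L, events$start_idx[i] - pad)
      hi <- min(n, events$end_idx[i] + pad)
      keep[lo:hi] <- FALSE
    }
  }
  idx <- which(keep)
  if (length(idx) < 2L) {
    warning("all samples removed by event exclusion; returning 0", call. = FALSE)
    return(0)
  }
  seg <- cumsum(c(1L, diff(idx) != 1L))
  diffs <- unlist(lapply(split(idx, seg), function(s) {
    if (length(s) >= 2L) diff(eog[s]) else numeric(0)
  }), use.names = FALSE)
  if (length(diffs) == 0L) {
    warning("no contiguous segment long enough after exclusion; returning 0",
            call. = FALSE)
    return(0)
  }
  .popvar(diffs)
}
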