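# Multiscale sample entropy of the denoised EEG epoch.

#' Coarse-grain a series
#'
#' Non-overlapping window means at scale `tau`; output length
#' `floor(length(x) / tau)`.
#'
#' @param x numeric series.
#' @param tau integer scale factor, at most `length(x)`.
#' @return numeric vector of window means.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  n <- length(x)
  if (tau < 1L || tau > n) stop("scale factor out of range", call. = FALSE)
  if (tau == 1L) return(x)
  nb <- n %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' \eqn{-\ln(A/B)} where `B` counts template pairs of length `m` and `A`
#' pairs of length `m + 1` within Chebyshev distance `r` (non-strict,
#' self-matches excluded; both counts range over the templates that admit an
#' `m + 1` extension). When no pairs match at either length the entropy is
#' undefined; a finite cap is returned with attribute `undefined = TRUE`.
#'
#' @param x numeric series, length greater than `m + 1`.
#' @param m template (embedding) length.
#' @param r absolute tolerance (same units as `x`), non-negative.
#' @param cap value returned when the entropy is undefined.
#' @return scalar entropy estimate.
#' @export
sample_entropy <- function(x, m = 2L, r, cap = 3.0) {
  n <- length(x)
  if (n <= m + 1L) stop("series too short for embedding length m", call. = FALSE)
  if (r < 0) stop("tolerance r must be non-negative", call. = FALSE)
  counts <- sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  B <- counts[1]; A <- counts[2]
  if (B == 0 || A == 0) {
    return(structure(cap, undefined = TRUE))
  }
  -log(A / B)
}

#' Multiscale sample entropy
#'
#' Sample entropy of the coarse-grained series at each scale in `scales`,
#' with tolerance \code{r = r_factor * sd(x)} fixed from the scale-1 series. The
#' default scales 9--13 give five entropy features per epoch.
#'
#' @param x numeric series (one epoch).
#' @param m embedding length (default 2).
#' @param r_factor tolerance as a fraction of the standard deviation.
#' @param scales integer scale factors.
#' @param cap value substituted for undefined entropies.
#' @return named numeric vector, `mse_<scale>` per scale.
#' @export
multiscale_entropy <- function(x, m = 2L, r_factor = 0.2, scales = 9:13,
                               cap = 3.0) {
  if (r_factor <= 0 || r_factor >= 1) stop("r_factor must be in (0, 1)", call. = FALSE)
  r <- r_factor * stats::sd(x)
  vals <- vapply(scales, function(tau) {
    as.numeric(sample_entropy(coarse_grain(x, tau), m = m, r = r, cap = cap))
  }, numeric(1))
  stats::setNames(vals, paste0("mse_", scales))
}
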