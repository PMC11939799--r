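# Orthogonal periodised discrete wavelet transform (Daubechies family) and
# universal soft-threshold denoising. Implemented here because the epoch
# denoiser needs only the classic Mallat pyramid; filters are the standard
# orthonormal Daubechies coefficients.

# db4 (8-tap) orthonormal scaling filter, sum = sqrt(2)
.DB4_H <- c(
   0.230377813308855230, 0.714846570552541500,
   0.630880767929590400, -0.027983769416983850,
  -0.187034811718881140, 0.030841381835986965,
   0.032883011666982945, -0.010597401784997278
)

.wavelet_filters <- function(basis = "db4") {
  h <- switch(basis,
    db4 = .DB4_H,
    stop("unsupported wavelet basis: ", basis, call. = FALSE)
  )
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)  # quadrature mirror highpass
  list(h = h, g = g, length = L)
}

# one analysis step on an even-length signal, circular (periodised) extension
.dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n / 2L
  L <- length(h)
  a <- numeric(half)
  d <- numeric(half)
  k <- 0:(half - 1L)
  for (m in 0:(L - 1L)) {
    idx <- (2L * k + m) %% n + 1L
    a <- a + h[m + 1L] * x[idx]
    d <- d + g[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

# transpose (synthesis) of .dwt_step; exact inverse for orthonormal filters
.idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2L * half
  L <- length(h)
  x <- numeric(n)
  k <- 0:(half - 1L)
  for (m in 0:(L - 1L)) {
    idx <- (2L * k + m) %% n + 1L
    x[idx] <- x[idx] + h[m + 1L] * a + g[m + 1L] * d
  }
  x
}

#' Discrete wavelet decomposition (periodised, orthonormal)
#'
#' Decomposes a signal into `levels` detail bands plus a final approximation
#' using the Mallat pyramid with circular extension. The signal length must be
#' divisible by `2^levels`; [wavelet_denoise()] handles arbitrary lengths by
#' symmetric padding.
#'
#' @param x numeric vector, length divisible by `2^levels`.
#' @param levels decomposition depth.
#' @param basis wavelet family identifier; only `"db4"` is provided.
#' @return list with `approx` (coarsest approximation) and `details`
#'   (list of detail coefficient vectors, finest scale first).
#' @keywords internal
dwt_periodised <- function(x, levels, basis = "db4") {
  f <- .wavelet_filters(basis)
  if (length(x) %% 2L^levels != 0L) {
    stop("signal length must be divisible by 2^levels", call. = FALSE)
  }
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- .dwt_step(a, f$h, f$g)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, basis = basis)
}

#' @rdname dwt_periodised
#' @param decomp a decomposition as returned by [dwt_periodised()].
#' @keywords internal
idwt_periodised <- function(decomp) {
  f <- .wavelet_filters(decomp$basis)
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- .idwt_step(a, decomp$details[[j]], f$h, f$g)
  }
  a
}

.soft_threshold <- function(d, thr) sign(d) * pmax(abs(d) - thr, 0)

#' Wavelet soft-threshold denoising
#'
#' Denoises a signal by db4 wavelet decomposition, soft thresholding of the
#' detail coefficients, and reconstruction. The universal threshold
#' \eqn{\sigma \sqrt{2 \log N}} is applied to every detail level, with the
#' noise scale \eqn{\sigma} estimated once from the finest detail level
#' (median absolute coefficient / 0.6745), where measurement noise dominates
#' and neural rhythms contribute least; estimating \eqn{\sigma} per level
#' would treat the broadband EEG itself as noise and flatten the spectrum
#' the downstream features depend on. Signals whose length is not divisible
#' by `2^levels` are symmetrically padded before the transform and cropped
#' afterwards.
#'
#' @param x numeric signal (finite values).
#' @param levels decomposition depth; `length(x)` must be at least `2^levels`.
#' @param basis wavelet family, default `"db4"`.
#' @return denoised numeric vector, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 30, by = 0.01)[-1]) + rnorm(3000, sd = 0.5)
#' y <- wavelet_denoise(x)
#' @export
wavelet_denoise <- function(x, levels = 7L, basis = "db4") {
  n <- length(x)
  if (n < 2L^levels) {
    stop("signal too short for a ", levels, "-level decomposition", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  block <- 2L^levels
  n_pad <- ceiling(n / block) * block
  pad <- n_pad - n
  left <- pad %/% 2L
  right <- pad - left
  xp <- .reflect_pad(x, left, right)

  dec <- dwt_periodised(xp, levels = levels, basis = basis)
  sigma <- stats::median(abs(dec$details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n_pad))
  for (j in seq_along(dec$details)) {
    dec$details[[j]] <- .soft_threshold(dec$details[[j]], thr)
  }
  y <- idwt_periodised(dec)
  y[(left + 1L):(left + n)]
}

# symmetric (reflection, no repeated edge sample) padding; falls back to
# edge replication when the requested pad exceeds the signal length
.reflect_pad <- function(x, left, right) {
  n <- length(x)
  take <- function(idx) {
    idx <- pmax(pmin(idx, n), 1L)
    x[idx]
  }
  lp <- if (left > 0L) take((left + 1L):2L) else numeric(0)
  rp <- if (right > 0L) take((n - 1L):(n - right)) else numeric(0)
  c(lp, x, rp)
}
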