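# Independent oracles and fixture builders used across the test files.

# literal brute-force sample entropy: triple loop over the written definition,
# kept deliberately independent of the package's compiled implementation
brute_sample_entropy <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  B <- 0
  A <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      db <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (db <= r) {
        B <- B + 1
        if (max(db, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

pop_var <- function(x) mean((x - mean(x))^2)

# analytic AR(2) spectral peak location on a dense grid
ar2_peak_freq <- function(a1, a2, fs, df = 0.001) {
  f <- seq(0, fs / 2, by = df)
  dens <- 1 / Mod(1 - a1 * exp(-2i * pi * f / fs) - a2 * exp(-4i * pi * f / fs))^2
  f[which.max(dens)]
}

# EOG fixture: quiet baseline with k planted biphasic deflections of given
# peak-to-peak amplitude and extrema interval
planted_eog <- function(k, fs = 100, n = 3000, p2p = 200, extrema_gap_s = 0.5,
                        baseline_sd = 2, seed = 42) {
  set.seed(seed)
  x <- rnorm(n, sd = baseline_sd)
  if (k == 0) return(x)
  period <- 2 * extrema_gap_s          # full sine period
  len <- round(period * fs)
  starts <- round(seq(from = 2 * fs, to = n - len - 2 * fs, length.out = k))
  for (s in starts) {
    x[s:(s + len - 1)] <- x[s:(s + len - 1)] +
      (p2p / 2) * sin(2 * pi * seq_len(len) / len)
  }
  x
}

# small separable feature tibble for selection/classifier/CV tests: each
# stage shifts the informative columns, noise columns are pure noise
toy_features <- function(n_subjects = 10, epochs_per_stage = 8,
                         n_informative = 3, n_noise = 5, sep = 4, seed = 1) {
  set.seed(seed)
  stages <- stage_levels()
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (st_i in seq_along(stages)) {
      k <- epochs_per_stage
      inf <- matrix(rnorm(k * n_informative, mean = sep * st_i), k)
      noi <- matrix(rnorm(k * n_noise), k)
      df <- tibble::as_tibble(cbind(inf, noi), .name_repair = "minimal")
      names(df) <- c(paste0("inf_", seq_len(n_informative)),
                     paste0("noise_", seq_len(n_noise)))
      df$subject_id <- sprintf("T%02d", s)
      df$night <- 1L
      df$epoch_index <- seq_len(k)
      df$stage <- stages[st_i]
      rows[[length(rows) + 1]] <- df
    }
  }
  dplyr::bind_rows(rows)
}
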