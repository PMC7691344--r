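# Independent brute-force oracles: plain-loop reimplementations of the
# index definitions, kept deliberately naive (lm() fits, explicit sums)
# so they share no code path with the package internals.

oracle_excursion <- function(w) {
  n <- length(w)
  r <- numeric(n)
  for (i in seq_len(n)) {
    # line through the first and last samples, evaluated pointwise
    line_i <- w[1] + (w[n] - w[1]) * (i - 1) / (n - 1)
    r[i] <- w[i] - line_i
  }
  max(r) - min(r)
}

oracle_phase <- function(x, y) {
  x <- x - mean(x)
  y <- y - mean(y)
  num <- 0; sx <- 0; sy <- 0
  for (i in seq_along(x)) {
    num <- num + x[i] * y[i]
    sx <- sx + x[i]^2
    sy <- sy + y[i]^2
  }
  acos(min(1, max(-1, num / sqrt(sx * sy)))) * 180 / pi
}

oracle_lbi <- function(x, y) {
  (oracle_excursion(x) + oracle_excursion(y)) / oracle_excursion(x + y)
}

oracle_rc_percent <- function(x, y) {
  100 * oracle_excursion(x) / (oracle_excursion(x) + oracle_excursion(y))
}

# Direct discrete Fourier sum |X[f]| of a mean-removed signal at one
# frequency (no FFT).
oracle_dft_mag <- function(x, f, fs, nfft) {
  x <- c(x - mean(x), numeric(nfft - length(x)))
  n <- seq_along(x) - 1
  re <- sum(x * cos(-2 * pi * f * n / fs))
  im <- sum(x * sin(-2 * pi * f * n / fs))
  sqrt(re^2 + im^2)
}

# k whole periods of two unit sinusoids at a given lag, spp samples per
# period (closed-form truth: phase angle = lag, LBI = 1/cos(lag/2)).
# closed = TRUE appends the period-closing sample (equal endpoints), the
# natural window for amplitude estimates; open windows keep the exact
# full-period orthogonality needed by the phase formula.
lagged_sines <- function(lag_deg, k = 1, spp = 20, closed = FALSE) {
  last <- k * spp - if (closed) 0 else 1
  th <- 2 * pi * (0:last) / spp
  list(x = sin(th), y = sin(th - lag_deg * pi / 180))
}

# Random smooth-ish test window: sinusoid mixture plus noise, never flat.
random_window <- function(n = 20) {
  th <- 2 * pi * (0:(n - 1)) / n
  f1 <- runif(1, 0.5, 3)
  sin(f1 * th + runif(1, 0, 2 * pi)) +
    runif(1, 0, 0.5) * sin(2 * f1 * th + runif(1, 0, 2 * pi)) +
    rnorm(n, sd = 0.1)
}

# Flat-loop recomputation of the cohort summary's windowed-index rows.
oracle_cohort_rows <- function(series_list) {
  out <- list()
  for (var in c("phase_deg", "rc_percent", "lbi")) {
    means <- numeric(0)
    for (s in series_list) {
      acc <- 0; cnt <- 0
      for (i in seq_len(nrow(s))) {
        if (s$valid[i]) { acc <- acc + s[[var]][i]; cnt <- cnt + 1 }
      }
      means <- c(means, acc / cnt)
    }
    out[[var]] <- c(mean = mean(means),
                    sem = if (length(means) > 1) sd(means) / sqrt(length(means)) else NA_real_)
  }
  out
}
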