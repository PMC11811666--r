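# Independent brute-force oracles used to cross-check the vectorized
# implementations. These are deliberately naive (double loops, full
# enumeration) and must never call the functions they check.

oracle_iv <- function(x) {
  n <- length(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  xb <- mean(x)
  den <- 0
  for (i in 1:n) den <- den + (x[i] - xb)^2
  n * num / ((n - 1) * den)
}

oracle_is <- function(x, p) {
  n <- length(x)
  xb <- mean(x)
  hod <- (seq_len(n) - 1) %% p
  num <- 0
  for (h in 0:(p - 1)) {
    if (any(hod == h)) num <- num + (mean(x[hod == h]) - xb)^2
  }
  den <- 0
  for (i in 1:n) den <- den + (x[i] - xb)^2
  n * num / (p * den)
}

# All moving-average values for window width w, one per start position.
oracle_moving_means <- function(x, w) {
  out <- numeric(length(x) - w + 1)
  for (i in seq_along(out)) out[i] <- mean(x[i:(i + w - 1)])
  out
}

# Exact two-sided rank-sum p-value by full enumeration of all rank subsets
# (valid for tie-free samples).
oracle_ranksum_p <- function(x, y) {
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(ix) sum(ix) - m * (m + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, if (u_obs > m * n / 2) 2 * p_hi else 2 * p_lo)
}

# Noise-free cosine sampled on an epoch grid.
make_cosine_series <- function(mesor = 75, amplitude = 10, acrophase = 15,
                               days = 2, epoch_minutes = 5, noise_sd = 0,
                               start = "2023-03-06") {
  n <- days * 1440 / epoch_minutes
  t_h <- (seq_len(n) - 1) * epoch_minutes / 60
  y <- mesor + amplitude * cos(2 * pi * (t_h - acrophase) / 24)
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
  epoch_series(y, start, epoch_minutes)
}

small_config <- function(...) {
  cohort_config(n_participants = 12, study_days = 3, seed = 42, ...)
}
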