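# Independent oracles used across tests.  These deliberately take different
# computational routes than the package implementations they check.

# Sample-entropy match counting via full pairwise Chebyshev distance
# matrices over windows (matrix algebra; the implementation is a C++
# pairwise loop with early abort).
oracle_count_matches <- function(y, m, r) {
  N <- length(y)
  T <- N - m
  cheb <- function(len) {
    D <- matrix(0, T, T)
    for (i in seq_len(len)) {
      seg <- y[(i - 1) + seq_len(T)]
      D <- pmax(D, abs(outer(seg, seg, "-")))
    }
    D
  }
  Dm <- cheb(m)
  Dm1 <- cheb(m - 1)
  diag(Dm) <- Inf; diag(Dm1) <- Inf
  c(c_m = sum(Dm <= r), c_m_minus_1 = sum(Dm1 <= r))
}

oracle_sample_entropy <- function(y, m, r) {
  y <- (y - mean(y)) / sd(y)
  cnt <- oracle_count_matches(y, m, r)
  if (cnt[1] > 0 && cnt[2] > 0) unname(-log(cnt[1] / cnt[2]))
  else -log((length(y) - m) / (length(y) - m - 1))
}

# Median frequency by explicit scan (no cumsum)
oracle_median_frequency <- function(P, M, fs, f_low, f_high) {
  k_low <- round(f_low * M / fs)
  k_high <- min(round(f_high * M / fs), floor(M / 2))
  ks <- (k_low + 1L):k_high
  total <- sum(P[ks + 1L])
  acc <- 0
  for (k in ks) {
    acc <- acc + P[k + 1L]
    if (acc >= total / 2) return(k * fs / M)
  }
  NA_real_
}

# In-band max by explicit scan
oracle_peak_amplitude <- function(P, M, fs, f_low, f_high) {
  k_low <- round(f_low * M / fs)
  k_high <- min(round(f_high * M / fs), floor(M / 2))
  best <- -Inf
  for (k in (k_low + 1L):k_high) best <- max(best, P[k + 1L])
  best
}

# construct a vector with exact sample mean mu and sample SD sigma
exact_moments <- function(n, mu, sigma) {
  z <- seq_len(n)
  z <- (z - mean(z)) / sd(z)
  mu + sigma * z
}

# small balanced two-class matrix: 2 informative + n_noise noise features
make_selection_problem <- function(n_per_class = 50, n_noise = 8, delta = 1.5,
                                   seed = 7) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- cbind(
    rnorm(n) + rep(c(0, delta), each = n_per_class),
    rnorm(n) + rep(c(0, delta), each = n_per_class),
    matrix(rnorm(n * n_noise), ncol = n_noise)
  )
  colnames(x) <- c("inf1", "inf2", paste0("noise", seq_len(n_noise)))
  list(x = x, y = factor(rep(c("a", "b"), each = n_per_class)))
}
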