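# Independent brute-force oracles used across test files.

# Discrete S-transform by direct summation: naive DFT of the signal, then
# for each voice k and output time j an explicit sum over frequency offsets
# m with the sampled Gaussian window. Deliberately loop-based and FFT-free.
stockwell_direct <- function(x, fs, f_lo = 0, f_hi = fs / 2) {
  n <- length(x)
  X <- vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)) / n, complex(1))
  df <- fs / n
  rows <- (0:(n %/% 2))[(0:(n %/% 2)) * df >= f_lo - 1e-12 &
                          (0:(n %/% 2)) * df <= f_hi + 1e-12]
  m <- 0:(n - 1)
  mw <- ifelse(m > n / 2, m - n, m)
  S <- matrix(0 + 0i, length(rows), n)
  for (i in seq_along(rows)) {
    k <- rows[i]
    if (k == 0) { S[i, ] <- mean(x); next }
    g <- exp(-2 * pi^2 * mw^2 / k^2)
    for (j in 0:(n - 1))
      S[i, j + 1] <- sum(X[(m + k) %% n + 1] * g * exp(2i * pi * m * j / n))
  }
  list(S = S, freq_hz = rows * df)
}

# O(N^2) pairwise phase consistency: the printed double loop over spike
# pairs, phases in cycles.
ppc_bruteforce <- function(phases_cycles) {
  th <- 2 * pi * phases_cycles
  n <- length(th)
  acc <- 0
  for (j in 1:(n - 1))
    for (k in (j + 1):n)
      acc <- acc + cos(th[j]) * cos(th[k]) + sin(th[j]) * sin(th[k])
  2 * acc / (n * (n - 1))
}

# Exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments on the observed absolute-difference ranks.
wilcoxon_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# band power of a signal via the periodogram (used as an independent check
# on generator band-power scaling)
band_power <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (0:(n - 1)) * fs / n
  sel <- f >= band[1] & f <= band[2]
  2 * sum(p[sel])
}
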