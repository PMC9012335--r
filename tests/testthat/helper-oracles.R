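# Independent oracles used across the suite. These recompute quantities from
# first principles (direct DFT sums, full enumeration) and deliberately share
# no code with the package implementation.

# O(N^2) one-sided power spectrum straight from the DFT definition,
# with the same Parseval scaling contract as power_spectrum():
# sum(one-sided power) == mean(v^2).
oracle_dft_spectrum <- function(v, fs) {
  n <- length(v)
  half <- n %/% 2L
  idx <- 0:half
  t_n <- 0:(n - 1L)
  power <- vapply(idx, function(k) {
    X <- sum(v * exp(-2i * pi * k * t_n / n))
    p <- Mod(X)^2 / n^2
    if (k != 0L && !(n %% 2L == 0L && k == half)) p <- 2 * p
    p
  }, numeric(1))
  list(frequencies = idx * fs / n, power = power)
}

oracle_band <- function(spec, f_lo, f_hi) {
  keep <- spec$frequencies >= f_lo - 1e-12 & spec$frequencies <= f_hi + 1e-12
  list(frequencies = spec$frequencies[keep], power = spec$power[keep])
}

# Spectral features computed directly on an oracle spectrum (left-bin median
# convention, lowest-frequency tie-break).
oracle_spectral_features <- function(spec) {
  f <- spec$frequencies; p <- spec$power
  tot <- sum(p)
  c(f_peak = f[which.max(p)],
    f_mean = sum(f * p) / tot,
    f_median = f[which(cumsum(p) >= tot / 2 - 1e-15 * tot)[1L]])
}

# Exact two-sided rank-sum p-value by full enumeration of all C(n, n1)
# equally likely rank assignments (valid for untied pooled samples).
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  ws <- utils::combn(n, n1, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Convenience builders.
tone_segment <- function(freq, fs, duration, amplitude = 1, phi = 0, ...) {
  t_s <- (seq_len(round(duration * fs)) - 1) / fs
  eug_segment(amplitude * cos(2 * pi * freq * t_s + phi), fs, ...)
}

random_segment <- function(n, fs = 32) {
  eug_segment(stats::rnorm(n, sd = 50), fs,
              recording_id = "rand", segment_index = 1L, phase = "PP")
}
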