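#' Butterworth lowpass design as cascaded second-order sections
#'
#' Designs a digital Butterworth lowpass of even order `order` with -3 dB
#' point at `cutoff` Hz for sampling rate `fs`, via the analog prototype
#' poles and the bilinear transform with frequency pre-warping. The filter
#' is returned as second-order sections (biquads) rather than a single
#' transfer function: at the normalized cutoffs used here
#' (0.1 Hz / 256 Hz ~ 8e-4 of the sampling rate) a direct-form realization
#' of an 8th-order polynomial is numerically unusable, while the SOS cascade
#' is stable in double precision.
#'
#' Each section has numerator `g * (1, 2, 1)` (both zeros at z = -1) and is
#' individually normalized to unit DC gain.
#'
#' @param order Filter order (even, >= 2).
#' @param cutoff -3 dB cutoff frequency, Hz.
#' @param fs Sampling rate, Hz; `cutoff` must be below `fs/2`.
#' @return Matrix with `order/2` rows and columns `b0,b1,b2,a1,a2`
#'   (denominator normalized to `a0 = 1`).
#' @export
butter_lowpass_sos <- function(order = 8L, cutoff = 0.1, fs = 256) {
  if (order < 2L || order %% 2L != 0L)
    stop("`order` must be an even integer >= 2")
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("`cutoff` must lie strictly between 0 and the Nyquist rate fs/2")
  wc <- 2 * fs * tan(pi * cutoff / fs)          # pre-warped analog cutoff
  k <- seq_len(order %/% 2L)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  s <- wc * complex(modulus = 1, argument = theta)  # upper-half-plane poles
  p <- (1 + s / (2 * fs)) / (1 - s / (2 * fs))      # bilinear transform
  a1 <- -2 * Re(p)
  a2 <- Mod(p)^2
  g <- (1 + a1 + a2) / 4                            # unit gain at z = 1
  cbind(b0 = g, b1 = 2 * g, b2 = g, a1 = a1, a2 = a2)
}

## One biquad, direct form; FIR part vectorized, IIR part via the C-level
## recursion in stats::filter. Zero initial state.
biquad_filter <- function(x, coef) {
  n <- length(x)
  v <- coef[["b0"]] * x
  if (n >= 2L) v[-1L] <- v[-1L] + coef[["b1"]] * x[-n]
  if (n >= 3L) v[-(1:2)] <- v[-(1:2)] + coef[["b2"]] * x[seq_len(n - 2L)]
  as.numeric(stats::filter(v, -c(coef[["a1"]], coef[["a2"]]),
                           method = "recursive"))
}

#' Apply a second-order-section filter cascade
#'
#' Runs `x` through the biquad cascade `sos`. The default mode is a causal
#' single pass with steady-state initialization: the cascade (which has unit
#' DC gain) is applied to `x - x[1]` with zero internal state and `x[1]` is
#' added back, which is exactly equivalent to starting every section in its
#' steady state for a constant input `x[1]`. This avoids the large start-up
#' transient a zero-state filter would produce on signals with offset, while
#' keeping the stated filter order. `zero_phase = TRUE` applies the cascade
#' forward and backward (squaring the magnitude response and doubling the
#' effective order, but cancelling phase delay).
#'
#' @param x Numeric vector.
#' @param sos SOS matrix from [butter_lowpass_sos()].
#' @param zero_phase Apply forward-backward filtering (default `FALSE`).
#' @return Filtered numeric vector, same length as `x`.
#' @export
sos_filter <- function(x, sos, zero_phase = FALSE) {
  run <- function(v) {
    for (i in seq_len(nrow(sos))) v <- biquad_filter(v, sos[i, ])
    v
  }
  x0 <- x[1L]
  y <- run(x - x0) + x0
  if (zero_phase) {
    y <- rev(y)
    y0 <- y[1L]
    y <- rev(run(y - y0) + y0)
  }
  y
}

#' Magnitude response of an SOS cascade
#'
#' Evaluates \eqn{|H(e^{j 2\pi f / fs})|} at the requested frequencies;
#' useful for verifying the designed attenuation (for an order-8 Butterworth
#' at cutoff \eqn{f_c}, \eqn{|H(f)|^2 = 1/(1 + (f/f_c)^{16})}, i.e. 48.2 dB
#' down at \eqn{2 f_c}).
#'
#' @param sos SOS matrix.
#' @param f Frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of linear magnitude gains.
#' @export
sos_gain <- function(sos, f, fs) {
  z1 <- exp(-2i * pi * f / fs)
  g <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, c("b0", "b1", "b2")]
    a <- c(1, sos[i, c("a1", "a2")])
    g <- g * (b[1] + b[2] * z1 + b[3] * z1^2) / (a[1] + a[2] * z1 + a[3] * z1^2)
  }
  Mod(g)
}
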