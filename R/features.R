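#' Root-mean-square voltage of a segment
#'
#' \deqn{V_{RMS} = \sqrt{\sum_{n=1}^{N} V^2[n] / N}}
#'
#' @param segment An `eug_segment`.
#' @return RMS voltage, \eqn{\mu}V.
#' @export
rms_voltage <- function(segment) {
  v <- segment$samples
  if (length(v) < 1L) stop("empty segment")
  sqrt(mean(v^2))
}

#' Peak (absolute) voltage of a segment
#'
#' \deqn{V_{peak} = \max |V[n]|}
#'
#' @param segment An `eug_segment`.
#' @return Peak voltage, \eqn{\mu}V.
#' @export
peak_voltage <- function(segment) {
  v <- segment$samples
  if (length(v) < 1L) stop("empty segment")
  max(abs(v))
}

#' Peak-to-peak voltage of a segment
#'
#' \deqn{V_{pp} = \max V[n] - \min V[n]}
#'
#' @param segment An `eug_segment`.
#' @return Peak-to-peak voltage, \eqn{\mu}V (always >= 0).
#' @export
peak_to_peak_voltage <- function(segment) {
  v <- segment$samples
  if (length(v) < 1L) stop("empty segment")
  max(v) - min(v)
}

#' One-sided periodogram power spectrum of a segment
#'
#' Computes the single full-length unwindowed periodogram on the DFT grid
#' (resolution `sampling_rate / N = 1 / duration`; 0.0033 Hz for a 5-minute
#' segment) and restricts it to the analysis band. Scaling is such that the
#' one-sided powers sum to the mean square of the signal (Parseval):
#' \deqn{P_k = c_k |X_k|^2 / N^2,\qquad c_k = 2} for interior bins and 1 for
#' the DC and (even-N) Nyquist bins.
#'
#' The default band is `(0, 0.1]` Hz: the DC bin is excluded (the mean is
#' removed upstream, and excluding numerical residue at 0 Hz keeps the mean
#' frequency well-defined) and the upper edge matches the lowpass cutoff, so
#' that stopband numerical residue cannot perturb the spectral features. Set
#' `band = NULL` for the full one-sided grid including DC.
#'
#' @param segment An `eug_segment` with at least 2 samples.
#' @param band Length-2 numeric `c(f_lo, f_hi)` in Hz, or `NULL` for the
#'   full grid. `NA` for `f_lo` means "first non-DC bin".
#' @return Object of class `eug_spectrum`: list with `frequencies` (Hz,
#'   strictly increasing), `power` (\eqn{\mu V^2}), `resolution` (Hz),
#'   `band`, and `total_power_full` (one-sided total before band
#'   restriction, equal to the segment mean square).
#' @export
power_spectrum <- function(segment, band = c(NA, 0.1)) {
  v <- segment$samples
  n <- length(v)
  if (n < 2L) stop("need at least 2 samples for a spectrum")
  fs <- segment$sampling_rate
  res <- fs / n
  nyq <- fs / 2
  X <- stats::fft(v)
  half <- n %/% 2L
  idx <- 0:half                       # one-sided bins
  p <- Mod(X[idx + 1L])^2 / n^2
  scale2 <- idx != 0L & !(n %% 2L == 0L & idx == half)
  p[scale2] <- 2 * p[scale2]
  freqs <- idx * res
  total_full <- sum(p)

  if (!is.null(band)) {
    if (length(band) != 2L) stop("`band` must be c(f_lo, f_hi) or NULL")
    f_lo <- if (is.na(band[1])) res else band[1]
    f_hi <- band[2]
    if (f_lo < 0 || f_hi > nyq + 1e-12 || f_hi <= 0)
      stop("band [", f_lo, ", ", f_hi, "] outside [0, Nyquist = ", nyq, "]")
    keep <- freqs >= f_lo - 1e-12 & freqs <= f_hi + 1e-12
    freqs <- freqs[keep]
    p <- p[keep]
  } else {
    f_lo <- 0; f_hi <- nyq
  }

  structure(list(frequencies = freqs, power = p, resolution = res,
                 band = c(f_lo, f_hi), total_power_full = total_full),
            class = "eug_spectrum")
}

#' @export
print.eug_spectrum <- function(x, ...) {
  cat(sprintf(
    "<eug_spectrum> %d bins in [%.4g, %.4g] Hz, resolution %.4g Hz\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$resolution))
  invisible(x)
}

#' Peak frequency of a power spectrum
#'
#' Frequency of the maximal-power bin; ties are broken toward the lowest
#' frequency.
#'
#' @param spectrum An `eug_spectrum`.
#' @return Peak frequency, Hz.
#' @export
peak_frequency <- function(spectrum) {
  if (length(spectrum$power) < 1L) stop("empty spectrum")
  if (all(spectrum$power <= 0)) stop("all-zero spectrum: peak undefined")
  spectrum$frequencies[which.max(spectrum$power)]
}

#' Mean (power-weighted) frequency of a power spectrum
#'
#' \deqn{f_{mean} = \sum_n f[n] P(f[n]) \big/ \sum_n P(f[n])}
#'
#' @param spectrum An `eug_spectrum`.
#' @return Mean frequency, Hz (need not lie on the DFT grid).
#' @export
mean_frequency <- function(spectrum) {
  tot <- sum(spectrum$power)
  if (length(spectrum$power) < 1L || tot <= 0)
    stop("zero total power: mean frequency undefined")
  sum(spectrum$frequencies * spectrum$power) / tot
}

#' Median frequency of a power spectrum
#'
#' The frequency splitting the spectral power into equal halves. On a
#' discrete grid exact balance rarely holds, so the left-bin convention is
#' used: the smallest grid frequency at which the cumulative power reaches
#' at least half of the total (no interpolation).
#'
#' @param spectrum An `eug_spectrum`.
#' @return Median frequency, Hz (always a grid frequency).
#' @export
median_frequency <- function(spectrum) {
  tot <- sum(spectrum$power)
  if (length(spectrum$power) < 1L || tot <= 0)
    stop("zero total power: median frequency undefined")
  cum <- cumsum(spectrum$power)
  spectrum$frequencies[which(cum >= tot / 2 - 1e-15 * tot)[1L]]
}

#' Extract the six per-segment features
#'
#' Computes the three amplitude features on the (preprocessed) time-domain
#' samples and the three spectral features on the band-restricted
#' periodogram. A segment with zero band power (e.g. an all-zero segment)
#' gets amplitude features of 0 but frequency features set to the missing
#' marker `NA` — never 0 — so degenerate segments are excluded from
#' downstream statistics rather than biasing them.
#'
#' @param segment Preprocessed `eug_segment`.
#' @param band Spectral analysis band passed to [power_spectrum()].
#' @return One-row `data.frame` with columns `recording_id`,
#'   `segment_index`, `phase`, `v_rms_uV`, `v_peak_uV`, `v_pp_uV`,
#'   `f_peak_hz`, `f_mean_hz`, `f_median_hz`.
#' @export
#' @examples
#' seg <- eug_segment(sin(2 * pi * 0.04 * (0:9599) / 32), 32,
#'                    recording_id = "demo", segment_index = 1, phase = "PP")
#' extract_features(seg)
extract_features <- function(segment, band = c(NA, 0.1)) {
  v_rms <- rms_voltage(segment)
  v_peak <- peak_voltage(segment)
  v_pp <- peak_to_peak_voltage(segment)

  spec <- power_spectrum(segment, band = band)
  if (sum(spec$power) <= 0) {
    f_peak <- f_mean <- f_median <- NA_real_
  } else {
    f_peak <- peak_frequency(spec)
    f_mean <- mean_frequency(spec)
    f_median <- median_frequency(spec)
  }

  data.frame(
    recording_id = segment$recording_id,
    segment_index = segment$segment_index,
    phase = segment$phase,
    v_rms_uV = v_rms,
    v_peak_uV = v_peak,
    v_pp_uV = v_pp,
    f_peak_hz = f_peak,
    f_mean_hz = f_mean,
    f_median_hz = f_median,
    stringsAsFactors = FALSE
  )
}

#' Names of the six feature columns
#'
#' Helper used by the comparison and reporting layers.
#' @return Character vector of the six feature column names.
#' @export
feature_names <- function() {
  c("v_rms_uV", "v_peak_uV", "v_pp_uV", "f_peak_hz", "f_mean_hz", "f_median_hz")
}
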