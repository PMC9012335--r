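#' Construct a segment object
#'
#' A segment is the unit of analysis: one channel, one fixed-duration window
#' of samples V\[n\] (n = 1..N, \eqn{\mu}V) at a known sampling rate, with
#' provenance metadata.
#'
#' @param samples Numeric vector, \eqn{\mu}V.
#' @param sampling_rate Hz.
#' @param recording_id,segment_index,phase,channel Provenance fields.
#' @return Object of class `eug_segment`.
#' @export
eug_segment <- function(samples, sampling_rate,
                        recording_id = NA_character_, segment_index = NA_integer_,
                        phase = NA_character_, channel = NA_integer_) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0")
  structure(list(
    samples = as.numeric(samples),
    sampling_rate = sampling_rate,
    duration = length(samples) / sampling_rate,
    recording_id = recording_id,
    segment_index = as.integer(segment_index),
    phase = phase,
    channel = as.integer(channel)
  ), class = "eug_segment")
}

#' @export
print.eug_segment <- function(x, ...) {
  cat(sprintf("<eug_segment> %s #%s: N = %d @ %g Hz (%.0f s), phase %s\n",
              x$recording_id, x$segment_index, length(x$samples),
              x$sampling_rate, x$duration, x$phase))
  invisible(x)
}

#' Cut a recording channel into sequential fixed-length segments
#'
#' Splits one channel of a recording into consecutive, non-overlapping
#' full-length windows starting at the first sample, keeping at most
#' `max_segments` windows and discarding any trailing partial window. The
#' defaults reproduce the standard protocol: 5-minute windows, maximum two
#' per recording (so a 10-minute recording yields 2 segments, a 7-minute one
#' yields 1, a 4-minute one yields none).
#'
#' @param recording An `eug_recording`.
#' @param channel Channel index to extract (default 1, the fundal electrode).
#' @param segment_duration Window length, s (default 300).
#' @param max_segments Cap on windows per recording (default 2).
#' @return List of `eug_segment` objects (possibly empty).
#' @export
segment_recording <- function(recording, channel = 1L,
                              segment_duration = 300, max_segments = 2L) {
  if (segment_duration <= 0) stop("`segment_duration` must be > 0")
  if (channel < 1L || channel > nrow(recording$samples))
    stop("invalid channel index ", channel, ": recording has ",
         nrow(recording$samples), " channel(s)")
  fs <- recording$sampling_rate
  x <- recording$samples[channel, ]
  win <- as.integer(round(segment_duration * fs))
  n_win <- min(length(x) %/% win, max_segments)
  if (n_win < 1L) return(list())
  lapply(seq_len(n_win), function(i) {
    eug_segment(x[((i - 1L) * win + 1L):(i * win)], fs,
                recording_id = recording$recording_id,
                segment_index = i,
                phase = recording$phase,
                channel = channel)
  })
}

#' Remove the mean value of a segment
#'
#' Only temporal voltage changes carry contraction information, so the DC
#' offset of each segment is discarded: V'\[n\] = V\[n\] - mean(V).
#'
#' @param segment An `eug_segment`.
#' @return Segment with zero-mean samples.
#' @export
subtract_mean <- function(segment) {
  if (length(segment$samples) < 1L) stop("empty segment")
  segment$samples <- segment$samples - mean(segment$samples)
  segment
}

#' Lowpass-filter a segment (8th-order Butterworth, 0.1 Hz)
#'
#' Applies the anti-artifact / anti-aliasing lowpass: an eighth-order
#' Butterworth with -3 dB point at `cutoff`, realised as cascaded
#' second-order sections ([butter_lowpass_sos()]) and applied as a causal
#' single pass with steady-state initialization (see [sos_filter()]).
#' Content above 0.1 Hz (mains, cardiac, respiration artifacts) is far above
#' the 6 contractions/min = 0.1 Hz physiological ceiling and is suppressed
#' by 48.2 dB already at 0.2 Hz.
#'
#' By default the input is extended backwards with a circular (wrap-around)
#' pre-pad, `9 / cutoff` seconds long, which is filtered and discarded: the
#' filter enters the segment warmed up on spectrally matched history instead
#' of ringing in from rest, and the output approaches the circular
#' convolution that the downstream periodogram implicitly assumes. Without
#' this, the start-up transient of an 8th-order filter at so low a cutoff
#' (settling over ~1 minute at 0.1 Hz) leaks measurable broadband power into
#' the stopband of broadband inputs, defeating the anti-aliasing guarantee.
#' The padding does not alter the filter's transfer function or its causal
#' single-pass character. Set `pad = "none"` for plain steady-state
#' initialization at the first sample.
#'
#' @param segment An `eug_segment`.
#' @param cutoff Cutoff, Hz (default 0.1); must be below Nyquist.
#' @param order Filter order (default 8).
#' @param zero_phase Use forward-backward filtering instead of a single
#'   causal pass (default `FALSE`; note this doubles the effective order).
#' @param pad Start-up handling: `"circular"` (default, wrap-around
#'   pre-padding) or `"none"`.
#' @return Filtered segment of identical length and rate.
#' @export
lowpass_filter <- function(segment, cutoff = 0.1, order = 8L,
                           zero_phase = FALSE, pad = c("circular", "none")) {
  pad <- match.arg(pad)
  fs <- segment$sampling_rate
  if (cutoff >= fs / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist rate ",
         fs / 2, " Hz")
  sos <- butter_lowpass_sos(order = order, cutoff = cutoff, fs = fs)
  x <- segment$samples
  n <- length(x)
  n_pad <- if (pad == "circular" && n > 1L)
    as.integer(round(9 / cutoff * fs)) else 0L
  if (n_pad > 0L) {
    idx <- ((n - n_pad + seq_len(n_pad) - 1L) %% n) + 1L
    x <- c(x[idx], x)
  }
  y <- sos_filter(x, sos, zero_phase = zero_phase)
  segment$samples <- y[(n_pad + 1L):(n_pad + n)]
  segment
}

#' Decimate a segment by an integer factor
#'
#' Keeps every `factor`-th sample starting at the first and divides the
#' sampling rate by `factor` (default x8: 256 Hz -> 32 Hz, so a 5-minute
#' segment of 76,800 samples becomes 9,600). No additional decimation filter
#' is applied: the 0.1 Hz lowpass upstream is the designated anti-aliasing
#' filter. Non-divisible lengths are truncated (output length `floor(N /
#' factor)`).
#'
#' @param segment An `eug_segment`, already lowpass filtered.
#' @param factor Integer decimation factor >= 1 (default 8).
#' @return Decimated segment at `sampling_rate / factor`.
#' @export
downsample <- function(segment, factor = 8L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be an integer >= 1")
  if (factor == 1L) return(segment)
  n_out <- length(segment$samples) %/% factor
  segment$samples <- segment$samples[(seq_len(n_out) - 1L) * factor + 1L]
  segment$sampling_rate <- segment$sampling_rate / factor
  segment$duration <- length(segment$samples) / segment$sampling_rate
  segment
}

#' Preprocessing parameter bundle
#'
#' @param cutoff_hz Lowpass cutoff, Hz.
#' @param order Butterworth order.
#' @param downsample_factor Integer decimation factor.
#' @param segment_duration_s Segmentation window, s.
#' @param max_segments_per_recording Cap on segments per recording.
#' @param channel Channel analysed.
#' @param zero_phase Forward-backward filtering flag.
#' @return A named list of class `eug_preprocess_params`.
#' @export
preprocess_params <- function(cutoff_hz = 0.1, order = 8L,
                              downsample_factor = 8L,
                              segment_duration_s = 300,
                              max_segments_per_recording = 2L,
                              channel = 1L, zero_phase = FALSE) {
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 downsample_factor = as.integer(downsample_factor),
                 segment_duration_s = segment_duration_s,
                 max_segments_per_recording = as.integer(max_segments_per_recording),
                 channel = as.integer(channel), zero_phase = zero_phase),
            class = "eug_preprocess_params")
}

#' Full per-segment preprocessing chain
#'
#' Composition, in order: [subtract_mean()], [lowpass_filter()],
#' [downsample()]. All three stages are linear, so the chain is linear and
#' offset-invariant.
#'
#' @param segment Raw `eug_segment` at acquisition rate.
#' @param params [preprocess_params()].
#' @return Processed segment (default: zero-mean, band-limited to 0.1 Hz,
#'   32 Hz rate).
#' @export
preprocess_segment <- function(segment, params = preprocess_params()) {
  seg <- subtract_mean(segment)
  seg <- lowpass_filter(seg, cutoff = params$cutoff_hz, order = params$order,
                        zero_phase = params$zero_phase)
  downsample(seg, factor = params$downsample_factor)
}
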