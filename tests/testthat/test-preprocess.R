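make_rec <- function(minutes, fs = 256, n_channels = 2) {
  n <- as.integer(minutes * 60 * fs)
  structure(list(samples = matrix(stats::rnorm(n * n_channels), nrow = n_channels),
                 sampling_rate = fs,
                 channel_labels = paste0("E", seq_len(n_channels)),
                 phase = "PP", recording_id = "fix", patient_id = "p1"),
            class = "eug_recording")
}

test_that("segmentation follows the 5-minute / max-2 windowing rule", {
  set.seed(1)
  expect_length(segment_recording(make_rec(12)), 2L)  # third window capped
  segs <- segment_recording(make_rec(7))
  expect_length(segs, 1L)                              # partial tail dropped
  expect_identical(length(segs[[1]]$samples), 300L * 256L)
  expect_length(segment_recording(make_rec(4)), 0L)    # no full window fits
  expect_error(segment_recording(make_rec(12), channel = 9), "invalid channel")

  # segments are consecutive from the start, with provenance
  rec <- make_rec(12)
  segs <- segment_recording(rec)
  expect_identical(segs[[1]]$samples, rec$samples[1, 1:76800])
  expect_identical(segs[[2]]$samples, rec$samples[1, 76801:153600])
  expect_identical(vapply(segs, `[[`, 0L, "segment_index"), 1:2)
  expect_identical(segs[[1]]$phase, "PP")
})

test_that("mean subtraction centres exactly", {
  seg <- eug_segment(c(1, 2, 3), 256)
  expect_equal(subtract_mean(seg)$samples, c(-1, 0, 1))
  expect_equal(subtract_mean(eug_segment(rep(5.5, 10), 256))$samples, rep(0, 10))
  centred <- eug_segment(c(-2, 0, 2), 256)
  expect_equal(subtract_mean(centred)$samples, centred$samples)
  set.seed(2)
  v <- rnorm(1000, mean = 40, sd = 300)
  out <- subtract_mean(eug_segment(v, 256))$samples
  expect_lt(abs(mean(out)), 1e-9 * max(1, max(abs(out))))
})

test_that("Butterworth lowpass has the designed magnitude response", {
  # steady-state attenuation of a 0.2 Hz tone: analytic
  # -10*log10(1 + (0.2/0.1)^16) = -48.165 dB, asserted within 1 dB
  seg <- tone_segment(0.2, 256, 600, amplitude = 100)
  y <- lowpass_filter(seg)$samples
  late <- y[(300 * 256):(600 * 256)]      # past the start-up transient
  att_db <- 20 * log10(sqrt(mean(late^2)) / (100 / sqrt(2)))
  expect_lt(abs(att_db + 48.165), 1)

  # 50 Hz mains tone crushed by > 80 dB
  seg50 <- tone_segment(50, 256, 60, amplitude = 100)
  rms_in <- sqrt(mean(seg50$samples^2))
  rms_out <- sqrt(mean(lowpass_filter(seg50)$samples[-(1:256)]^2))
  expect_lt(rms_out, 1e-4 * rms_in)

  # zero in, zero out; cutoff at/above Nyquist rejected
  expect_equal(lowpass_filter(eug_segment(numeric(100), 256))$samples,
               numeric(100))
  expect_error(lowpass_filter(eug_segment(rnorm(10), 256), cutoff = 128),
               "Nyquist")
})

test_that("SOS design matches the analytic Butterworth magnitude", {
  sos <- butter_lowpass_sos(8, 0.1, 256)
  f <- c(0.02, 0.05, 0.1, 0.15, 0.2, 0.5)
  expect_equal(sos_gain(sos, f, 256), 1 / sqrt(1 + (f / 0.1)^16),
               tolerance = 1e-6)
  expect_error(butter_lowpass_sos(7, 0.1, 256), "even")
})

test_that("decimation keeps every k-th sample and rescales the rate", {
  seg <- eug_segment(seq_len(76800), 256)
  out <- downsample(seg, 8)
  expect_identical(length(out$samples), 9600L)
  expect_equal(out$sampling_rate, 32)
  expect_equal(out$duration, 300)
  expect_identical(out$samples[1:3], c(1, 9, 17))

  expect_identical(downsample(seg, 1), seg)
  const <- downsample(eug_segment(rep(2.5, 100), 256), 8)
  expect_equal(const$samples, rep(2.5, 12))
  expect_error(downsample(seg, 0), "factor")
})

test_that("full chain removes offset and preserves in-band tones", {
  # constant offset + 0.04 Hz tone: offset goes, tone survives within the
  # passband ripple (|H(0.04)| deviates from 1 by < 1e-6)
  t_s <- (0:76799) / 256
  seg <- eug_segment(40 + 100 * cos(2 * pi * 0.04 * t_s), 256)
  out <- preprocess_segment(seg)
  expect_identical(length(out$samples), 9600L)
  spec <- power_spectrum(out, band = NULL)
  k <- which.min(abs(spec$frequencies - 0.04))
  expect_equal(spec$frequencies[k], 0.04)
  # tone power in its bin: A^2/2 for a bin-aligned tone (phase-shifted by the
  # causal filter but magnitude-preserved); 2% headroom covers the edge
  # transient of the causal single-pass filter
  expect_equal(spec$power[k], 100^2 / 2, tolerance = 0.02)
  expect_lt(spec$power[1], 1e-4 * spec$power[k])  # DC removed

  # zero in, zero out through the whole chain
  expect_equal(preprocess_segment(eug_segment(numeric(76800), 256))$samples,
               numeric(9600))
})

test_that("chain is linear and offset-invariant", {
  set.seed(42)
  x <- eug_segment(rnorm(76800, sd = 100), 256)
  y <- eug_segment(rnorm(76800, sd = 100), 256)
  a <- 2.5; b <- -1.3
  lhs <- preprocess_segment(eug_segment(a * x$samples + b * y$samples, 256))
  rhs <- a * preprocess_segment(x)$samples + b * preprocess_segment(y)$samples
  expect_equal(lhs$samples, rhs, tolerance = 1e-9)

  shifted <- preprocess_segment(eug_segment(x$samples + 1234.5, 256))
  expect_equal(shifted$samples, preprocess_segment(x)$samples,
               tolerance = 1e-9)
})

test_that("anti-aliasing: post-decimation power above 0.15 Hz is < 2%", {
  set.seed(7)
  for (i in 1:3) {
    seg <- eug_segment(rnorm(76800, sd = 50), 256)
    out <- preprocess_segment(seg)
    spec <- power_spectrum(out, band = NULL)
    frac <- sum(spec$power[spec$frequencies > 0.15]) / sum(spec$power)
    expect_lt(frac, 0.02)
  }
})
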