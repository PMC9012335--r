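test_that("amplitude features match their definitions", {
  expect_equal(rms_voltage(eug_segment(c(3, -4), 32)), sqrt(25 / 2))
  expect_equal(rms_voltage(eug_segment(numeric(10), 32)), 0)
  expect_equal(peak_voltage(eug_segment(c(-3, 1, 2), 32)), 3)
  expect_equal(peak_to_peak_voltage(eug_segment(c(-3, 1, 2), 32)), 5)
  expect_equal(peak_to_peak_voltage(eug_segment(rep(7, 5), 32)), 0)
  expect_error(rms_voltage(eug_segment(numeric(0), 32)), "empty")

  # 100 uV sinusoid over integer cycles: RMS = A/sqrt(2); the sample grid
  # t = 0 hits the cosine extremum, so V_peak = A and V_pp = 2A
  seg <- tone_segment(0.05, 32, 300, amplitude = 100)
  expect_equal(rms_voltage(seg), 100 / sqrt(2), tolerance = 1e-4)
  expect_equal(peak_voltage(seg), 100)
  expect_equal(peak_to_peak_voltage(seg), 200, tolerance = 1e-6)
})

test_that("periodogram has the stated resolution, scaling and banding", {
  set.seed(10)
  seg <- random_segment(9600, fs = 32)      # the canonical 5-min processed segment
  spec <- power_spectrum(seg)
  expect_equal(spec$resolution, 1 / 300)
  expect_equal(signif(spec$resolution, 2), 0.0033)
  expect_true(all(diff(spec$frequencies) > 0))
  expect_true(all(spec$power >= 0))
  # default band excludes DC and stops at the 0.1 Hz cutoff
  expect_equal(min(spec$frequencies), 1 / 300)
  expect_lte(max(spec$frequencies), 0.1 + 1e-12)

  # Parseval over the full one-sided grid
  full <- power_spectrum(seg, band = NULL)
  expect_equal(sum(full$power), mean(seg$samples^2), tolerance = 1e-9)
  expect_equal(full$total_power_full, mean(seg$samples^2), tolerance = 1e-9)

  # a bin-aligned tone concentrates in a single bin
  tone <- tone_segment(0.05, 32, 300, amplitude = 10)
  sp <- power_spectrum(tone, band = NULL)
  k <- which.min(abs(sp$frequencies - 0.05))
  expect_lt(max(sp$power[-k]), 1e-10 * sp$power[k])

  expect_error(power_spectrum(seg, band = c(0, 20)), "Nyquist")
})

test_that("spectral feature conventions: argmax, weighting, left-bin median", {
  t_s <- (0:9599) / 32
  mk <- function(v) power_spectrum(eug_segment(v, 32))

  # dominant bin wins
  two <- mk(2 * cos(2 * pi * 0.02 * t_s) + 1 * cos(2 * pi * 0.06 * t_s))
  expect_equal(peak_frequency(two), 0.02)
  # single tone: all three collapse to it
  one <- mk(cos(2 * pi * 0.05 * t_s))
  expect_equal(peak_frequency(one), 0.05)
  expect_equal(mean_frequency(one), 0.05, tolerance = 1e-9)
  expect_equal(median_frequency(one), 0.05)

  # exact ties cannot survive FFT rounding, so the conventions are pinned
  # on directly constructed spectra with bit-equal powers
  mk_spec <- function(f, p) structure(
    list(frequencies = f, power = p, resolution = f[2] - f[1],
         band = range(f), total_power_full = sum(p)),
    class = "eug_spectrum")
  tie <- mk_spec(c(0.02, 0.04, 0.06), c(5, 0, 5))
  expect_equal(peak_frequency(tie), 0.02)     # tie -> lowest frequency
  expect_equal(mean_frequency(tie), 0.04)     # symmetric average
  expect_equal(median_frequency(tie), 0.02)   # half reached at lower bin
  three <- mk_spec(c(0.01, 0.03, 0.05), c(2, 2, 2))
  expect_equal(median_frequency(three), 0.03) # half crossed at middle bin

  zero <- power_spectrum(eug_segment(numeric(9600), 32))
  expect_error(peak_frequency(zero), "undefined")
  expect_error(mean_frequency(zero), "undefined")
  expect_error(median_frequency(zero), "undefined")
})

test_that("extract_features populates, flags degenerate input, scales", {
  seg <- tone_segment(0.04, 32, 300, amplitude = 100,
                      recording_id = "r1", segment_index = 1L, phase = "PP")
  fv <- extract_features(seg)
  expect_identical(fv$recording_id, "r1")
  expect_equal(fv$f_peak_hz, 0.04)
  expect_equal(fv$v_rms_uV, 100 / sqrt(2), tolerance = 1e-4)

  # zero segment: amplitudes 0, frequencies are the NA missing marker
  z <- extract_features(eug_segment(numeric(9600), 32))
  expect_equal(z$v_rms_uV, 0)
  expect_true(is.na(z$f_peak_hz) && is.na(z$f_mean_hz) && is.na(z$f_median_hz))

  # scale equivariance: amplitudes x k, frequencies untouched
  k <- 4.2
  seg_k <- eug_segment(k * seg$samples, 32, recording_id = "r1",
                       segment_index = 1L, phase = "PP")
  fk <- extract_features(seg_k)
  expect_equal(fk$v_rms_uV, k * fv$v_rms_uV)
  expect_equal(fk$v_peak_uV, k * fv$v_peak_uV)
  expect_equal(fk$v_pp_uV, k * fv$v_pp_uV)
  expect_identical(fk$f_peak_hz, fv$f_peak_hz)
  expect_identical(fk$f_median_hz, fv$f_median_hz)
  expect_equal(fk$f_mean_hz, fv$f_mean_hz, tolerance = 1e-12)
})

test_that("feature ordering and range invariants hold on random segments", {
  set.seed(33)
  for (i in 1:25) {
    seg <- random_segment(sample(64:512, 1), fs = 32)
    fv <- extract_features(seg, band = c(NA, 16))
    expect_lte(fv$v_peak_uV, fv$v_pp_uV)
    expect_lte(fv$v_pp_uV, 2 * fv$v_peak_uV)
    res <- seg$sampling_rate / length(seg$samples)
    expect_gte(fv$f_mean_hz, res)
    expect_lte(fv$f_mean_hz, 16)
    # f_peak and f_median sit on the DFT grid
    expect_lt(min(abs(fv$f_peak_hz / res - round(fv$f_peak_hz / res))), 1e-9)
    expect_lt(min(abs(fv$f_median_hz / res - round(fv$f_median_hz / res))), 1e-9)
  }
})

test_that("spectral features match the O(N^2) direct-DFT oracle", {
  # 200 random segments, lengths 64-512 plus a few long ones (<= 2048);
  # full non-DC band so every bin participates
  set.seed(99)
  lens <- c(sample(64:512, 196, replace = TRUE), 1024L, 1500L, 2047L, 2048L)
  for (n in lens) {
    fs <- sample(c(16, 32, 64), 1)
    seg <- random_segment(n, fs = fs)
    spec <- power_spectrum(seg, band = c(NA, fs / 2))
    ora <- oracle_band(oracle_dft_spectrum(seg$samples, fs), fs / n, fs / 2)
    expect_equal(sum(spec$power), sum(ora$power), tolerance = 1e-9)
    of <- oracle_spectral_features(ora)
    expect_equal(peak_frequency(spec), of[["f_peak"]], tolerance = 1e-9)
    expect_equal(mean_frequency(spec), of[["f_mean"]], tolerance = 1e-9)
    expect_equal(median_frequency(spec), of[["f_median"]], tolerance = 1e-9)
  }
})
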