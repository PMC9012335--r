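#' Generator configuration for synthetic uterine EMG recordings
#'
#' Builds and validates the parameter bundle that fully determines one
#' simulated multichannel intrauterine EMG recording. The signal model on
#' electrode 1 is
#' \deqn{V(t) = A\, m(t)\cos(2\pi f_c t + \phi) + \mathrm{bursts}(t)
#'   + \mathrm{drift}(t) + \mathrm{artifacts}(t) + \mathrm{noise}(t)}
#' where \eqn{f_c} is the contraction rhythm in Hz
#' (`contraction_rate / 60`), \eqn{A} the slow-wave amplitude in \eqn{\mu}V
#' and \eqn{m(t)} a positive raised-cosine modulation envelope with mean 1
#' (depth `envelope_depth` at \eqn{f_c/4}). Burst activity is band-limited
#' (0.5--5 Hz) white noise gated where the slow wave exceeds its 70th
#' percentile; drift is a sum of up to three random sinusoids below
#' \eqn{f_c/4}; artifact tones sit at 50 Hz (mains), `cardiac_rate` and
#' `respiration_rate`.
#'
#' Healthy non-pregnant uterine peristalsis spans 0.8--6 contractions per
#' minute; rates outside that range are accepted but flagged via the
#' `physiological` element of the returned config (the default luteal preset
#' rate 0.4/min is itself sub-physiological, matching observed luteal-phase
#' peak frequencies around 0.0067 Hz).
#'
#' @param phase Cycle phase label, `"PP"` (proliferative) or `"LP"` (luteal).
#' @param contraction_rate Contraction rhythm, contractions/min (> 0).
#' @param rate_jitter Fractional (log-scale) sd of the rate across recordings
#'   in a cohort; applied by [generate_cohort()], not here.
#' @param slow_wave_amplitude Slow-wave peak amplitude \eqn{A}, \eqn{\mu}V.
#' @param amplitude_dispersion Log-normal sdlog of the amplitude across
#'   recordings in a cohort; applied by [generate_cohort()].
#' @param spike_burst_amplitude sd of the gated burst component, \eqn{\mu}V.
#' @param drift_amplitude Total baseline drift amplitude, \eqn{\mu}V.
#' @param noise_sd White sensor noise sd, \eqn{\mu}V.
#' @param mains_amplitude 50 Hz interference amplitude, \eqn{\mu}V.
#' @param cardiac_amplitude,cardiac_rate Cardiac artifact tone amplitude
#'   (\eqn{\mu}V) and rate (Hz, default 1.2, i.e. 72 bpm).
#' @param respiration_amplitude,respiration_rate Respiration artifact tone
#'   amplitude (\eqn{\mu}V) and rate (Hz, default 0.25, i.e. 15 breaths/min).
#' @param envelope_depth Raised-cosine modulation depth of \eqn{m(t)} in
#'   `[0, 1)`; 0 gives the unmodulated pure slow wave \eqn{m(t) \equiv 1}.
#' @param sampling_rate Acquisition rate, Hz (default 256).
#' @param duration Recording length, s (default 600); `duration *
#'   sampling_rate` must be a whole number of samples.
#' @param n_channels Number of electrodes simulated (default 7).
#' @param seed Integer seed; the recording is fully determined by it.
#' @return An object of class `eug_config` (a validated named list with the
#'   extra logical element `physiological`).
#' @seealso [phase_preset()], [generate_recording()], [generate_cohort()]
#' @export
#' @examples
#' cfg <- eug_config(phase = "PP", contraction_rate = 2.4,
#'                   slow_wave_amplitude = 275, seed = 1)
#' cfg$physiological
eug_config <- function(phase = c("PP", "LP"),
                       contraction_rate,
                       rate_jitter = 0,
                       slow_wave_amplitude,
                       amplitude_dispersion = 0,
                       spike_burst_amplitude = 0,
                       drift_amplitude = 0,
                       noise_sd = 0,
                       mains_amplitude = 0,
                       cardiac_amplitude = 0,
                       cardiac_rate = 1.2,
                       respiration_amplitude = 0,
                       respiration_rate = 0.25,
                       envelope_depth = 0.5,
                       sampling_rate = 256,
                       duration = 600,
                       n_channels = 7,
                       seed = 1L) {
  phase <- match.arg(phase)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("invalid config: `duration` must be a positive scalar (seconds)")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("invalid config: `sampling_rate` must be a positive scalar (Hz)")
  n_samples <- duration * sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("invalid config: duration * sampling_rate must be an integer ",
         "sample count (got ", n_samples, ")")
  if (contraction_rate <= 0)
    stop("invalid config: `contraction_rate` must be > 0")
  amps <- c(slow_wave_amplitude = slow_wave_amplitude,
            spike_burst_amplitude = spike_burst_amplitude,
            drift_amplitude = drift_amplitude,
            noise_sd = noise_sd,
            mains_amplitude = mains_amplitude,
            cardiac_amplitude = cardiac_amplitude,
            respiration_amplitude = respiration_amplitude)
  bad <- names(amps)[!is.finite(amps) | amps < 0]
  if (length(bad))
    stop("invalid config: amplitude fields must be finite and >= 0: ",
         paste(bad, collapse = ", "))
  if (rate_jitter < 0 || amplitude_dispersion < 0)
    stop("invalid config: dispersion fields must be >= 0")
  if (envelope_depth < 0 || envelope_depth >= 1)
    stop("invalid config: `envelope_depth` must be in [0, 1)")
  if (n_channels < 1) stop("invalid config: `n_channels` must be >= 1")

  structure(list(
    phase = phase,
    contraction_rate = contraction_rate,
    rate_jitter = rate_jitter,
    slow_wave_amplitude = slow_wave_amplitude,
    amplitude_dispersion = amplitude_dispersion,
    spike_burst_amplitude = spike_burst_amplitude,
    drift_amplitude = drift_amplitude,
    noise_sd = noise_sd,
    mains_amplitude = mains_amplitude,
    cardiac_amplitude = cardiac_amplitude,
    cardiac_rate = cardiac_rate,
    respiration_amplitude = respiration_amplitude,
    respiration_rate = respiration_rate,
    envelope_depth = envelope_depth,
    sampling_rate = sampling_rate,
    duration = duration,
    n_channels = as.integer(n_channels),
    seed = as.integer(seed),
    # 0.8-6 contractions/min is the physiological peristalsis range for
    # healthy non-pregnant women; outside values are accepted but flagged.
    physiological = contraction_rate >= 0.8 && contraction_rate <= 6.0
  ), class = "eug_config")
}

#' Default generator presets for the proliferative and luteal phases
#'
#' Named parameter bundles reflecting the phase contrast reported for
#' intrauterine recordings: the luteal phase (LP) shows larger-amplitude,
#' slower electrical activity than the proliferative phase (PP). Defaults are
#' calibrated so that median processed-segment features land near observed
#' values: PP rhythm 2.4 contractions/min (0.04 Hz) at ~275 uV slow-wave
#' amplitude, LP rhythm 0.4/min (~0.0067 Hz) at ~600 uV. Dispersion across
#' recordings is log-normal in amplitude (sdlog 0.25) with log-scale rate
#' jitter (sd 0.15).
#'
#' @param phase `"PP"` or `"LP"`.
#' @param ... Overrides passed on to [eug_config()].
#' @return An `eug_config` for the requested phase.
#' @export
#' @examples
#' pp <- phase_preset("PP")
#' lp <- phase_preset("LP")
#' stopifnot(lp$slow_wave_amplitude > pp$slow_wave_amplitude,
#'           pp$contraction_rate > lp$contraction_rate)
phase_preset <- function(phase = c("PP", "LP"), ...) {
  phase <- match.arg(phase)
  base <- list(
    phase = phase,
    rate_jitter = 0.15,
    amplitude_dispersion = 0.25,
    drift_amplitude = 40,
    noise_sd = 15,
    mains_amplitude = 10,
    cardiac_amplitude = 15,
    respiration_amplitude = 20,
    envelope_depth = 0.5,
    duration = 600
  )
  ph <- if (phase == "PP") {
    list(contraction_rate = 2.4, slow_wave_amplitude = 275,
         spike_burst_amplitude = 80)
  } else {
    list(contraction_rate = 0.4, slow_wave_amplitude = 600,
         spike_burst_amplitude = 180)
  }
  args <- utils::modifyList(c(base, ph), list(...))
  do.call(eug_config, args)
}

## FFT-mask bandpass used only inside the generator: exact, zero-phase and
## deterministic given the input draw; output renormalised to unit sd.
band_limited_noise <- function(z, fs, f_lo = 0.5, f_hi = 5) {
  n <- length(z)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  keep <- f >= f_lo & f <= f_hi
  if (!any(keep)) return(numeric(n))
  x <- Re(stats::fft(stats::fft(z) * keep, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate one synthetic multichannel uterine EMG recording
#'
#' Simulates `n_channels` electrode traces at `sampling_rate` for `duration`
#' seconds according to the model described in [eug_config()]. Channel 1 is
#' the analysis channel (closest to the fundus); channels 2..K are
#' amplitude-attenuated (factor 0.85 per electrode), time-lagged (2 s per
#' electrode) copies of the deterministic part of channel 1 plus independent
#' sensor noise — a crude propagation stand-in, as only channel 1 is analysed
#' downstream.
#'
#' All random draws are made unconditionally and scaled by their amplitude
#' parameters afterwards, so the recording is bit-reproducible for a given
#' `(config, seed)` and scales linearly when all amplitude fields are scaled
#' together.
#'
#' @param config An [eug_config()] (or [phase_preset()]) object.
#' @return An object of class `eug_recording`: list with `samples`
#'   (`n_channels x N` matrix, \eqn{\mu}V), `sampling_rate`,
#'   `channel_labels` (`"E1"`..), `phase`, `recording_id`, `patient_id`,
#'   and the generating `config`.
#' @export
#' @examples
#' rec <- generate_recording(eug_config(phase = "PP", contraction_rate = 2.4,
#'                                      slow_wave_amplitude = 275,
#'                                      duration = 60, seed = 7))
#' dim(rec$samples)  # 7 x 15360
generate_recording <- function(config) {
  if (!inherits(config, "eug_config"))
    config <- do.call(eug_config, config)
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration * fs))
  t <- (seq_len(n) - 1) / fs
  fc <- config$contraction_rate / 60

  set.seed(config$seed)
  ## fixed draw order: phases, drift geometry, burst noise, channel noise
  phi   <- stats::runif(1, 0, 2 * pi)     # slow-wave carrier
  phi_m <- stats::runif(1, 0, 2 * pi)     # envelope
  phi_a <- stats::runif(3, 0, 2 * pi)     # mains / cardiac / respiration
  k_drift <- sample(1:3, 1)
  f_drift <- stats::runif(3, fc / 40, fc / 4)
  phi_drift <- stats::runif(3, 0, 2 * pi)
  w_drift <- stats::runif(3); w_drift <- w_drift / sum(w_drift)
  z_burst <- stats::rnorm(n)
  z_noise <- matrix(stats::rnorm(n * config$n_channels), nrow = config$n_channels)

  m <- 1 + config$envelope_depth * cos(2 * pi * (fc / 4) * t + phi_m)
  slow <- config$slow_wave_amplitude * m * cos(2 * pi * fc * t + phi)

  ## bursts ride on the depolarising crest of the slow wave
  gate <- slow > stats::quantile(slow, 0.7)
  bursts <- config$spike_burst_amplitude *
    band_limited_noise(z_burst, fs) * as.numeric(gate)

  drift <- numeric(n)
  for (j in seq_len(k_drift))
    drift <- drift + w_drift[j] * sin(2 * pi * f_drift[j] * t + phi_drift[j])
  drift <- config$drift_amplitude * drift

  artifacts <- config$mains_amplitude * sin(2 * pi * 50 * t + phi_a[1]) +
    config$cardiac_amplitude * sin(2 * pi * config$cardiac_rate * t + phi_a[2]) +
    config$respiration_amplitude *
      sin(2 * pi * config$respiration_rate * t + phi_a[3])

  clean <- slow + bursts + drift + artifacts
  lag_samples <- as.integer(round(2 * fs))   # 2 s inter-electrode lag

  samples <- matrix(0, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    shifted <- if (ch == 1L) clean else {
      sh <- ((ch - 1L) * lag_samples) %% n
      if (sh == 0L) clean else c(clean[(n - sh + 1L):n], clean[1L:(n - sh)])
    }
    samples[ch, ] <- 0.85^(ch - 1) * shifted + config$noise_sd * z_noise[ch, ]
  }

  structure(list(
    samples = samples,
    sampling_rate = fs,
    channel_labels = paste0("E", seq_len(config$n_channels)),
    phase = config$phase,
    recording_id = sprintf("%s_seed%d", config$phase, config$seed),
    patient_id = sprintf("sim%03d", config$seed %% 1000L),
    config = config
  ), class = "eug_recording")
}

#' @export
print.eug_recording <- function(x, ...) {
  cat(sprintf(
    "<eug_recording> %s: %d channel(s) x %d samples @ %g Hz (%.1f min), phase %s\n",
    x$recording_id, nrow(x$samples), ncol(x$samples), x$sampling_rate,
    ncol(x$samples) / x$sampling_rate / 60, x$phase))
  invisible(x)
}

#' Generate a two-phase cohort of synthetic recordings
#'
#' Draws `n_pp` proliferative-phase and `n_lp` luteal-phase recordings.
#' Per-recording parameters vary around the presets: the slow-wave amplitude
#' is multiplied by a log-normal factor (`sdlog = amplitude_dispersion`,
#' median 1) and the contraction rate by `exp(rnorm(1, 0, rate_jitter))`.
#' Child seeds are spawned from the master seed as
#' `sample.int(2^31 - 2, n_pp + n_lp)` under `set.seed(seed)`, indexed by
#' recording number, so cohorts are reproducible across platforms and
#' independent of generation order.
#'
#' @param preset_pp,preset_lp `eug_config` objects for the two phases
#'   (defaults: [phase_preset()]).
#' @param n_pp,n_lp Cohort sizes (defaults 11 and 15 recordings).
#' @param seed Master seed for the cohort.
#' @return A list of `eug_recording` objects (PP first, then LP), each
#'   labelled with its phase and a unique `recording_id`.
#' @export
#' @examples
#' coh <- generate_cohort(n_pp = 2, n_lp = 2, seed = 1)
#' vapply(coh, function(r) r$phase, "")
generate_cohort <- function(preset_pp = phase_preset("PP"),
                            preset_lp = phase_preset("LP"),
                            n_pp = 11L, n_lp = 15L, seed = 1L) {
  if (n_pp < 1L || n_lp < 1L) stop("cohort sizes must be >= 1")
  n_tot <- n_pp + n_lp
  set.seed(seed)
  child_seeds <- sample.int(2^31 - 2, n_tot)
  presets <- c(rep(list(preset_pp), n_pp), rep(list(preset_lp), n_lp))

  out <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    p <- presets[[i]]
    set.seed(child_seeds[i])
    rate_i <- p$contraction_rate * exp(stats::rnorm(1, 0, p$rate_jitter))
    amp_i <- p$slow_wave_amplitude * exp(stats::rnorm(1, 0, p$amplitude_dispersion))
    cfg <- p
    cfg$contraction_rate <- rate_i
    cfg$slow_wave_amplitude <- amp_i
    cfg$physiological <- rate_i >= 0.8 && rate_i <= 6.0
    cfg$seed <- child_seeds[i]
    rec <- generate_recording(cfg)
    rec$recording_id <- sprintf("%s_r%02d", p$phase, i)
    rec$patient_id <- sprintf("sim%03d", i)
    out[[i]] <- rec
  }
  out
}
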