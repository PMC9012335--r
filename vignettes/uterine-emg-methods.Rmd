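---
title: "Methods: simulating and analysing intrauterine EMG across the menstrual cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing intrauterine EMG across the menstrual cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uemg)
```

## The problem

Uterine peristalsis — the slow, wave-like contractile activity of the
non-pregnant uterus — changes across the menstrual cycle and is relevant to
fertility assessment. Like any muscle activity, it is driven by electrical
depolarisation, which an intrauterine electrode array can record directly
from the junctional-zone endometrium as a multichannel voltage signal
(microvolts, sampled at 256 Hz). In healthy non-pregnant women the
contraction rhythm lies between 0.8 and 6 contractions per minute, i.e.
roughly 0.013–0.1 Hz: far below cardiac (~1.2 Hz), respiratory (~0.25 Hz)
and mains (50 Hz) interference, which is what makes a simple lowpass design
workable.

The analysis contrast of interest is between the **proliferative phase**
(PP; from menstruation to ovulation) and the **luteal phase** (LP; from
ovulation to the next menstruation): intrauterine recordings show
lower-amplitude, faster rhythms in PP and larger-amplitude, slower rhythms
in LP. `uemg` packages (i) a synthetic-data generator that emulates such
recordings, (ii) the preprocessing and six-feature extraction pipeline, and
(iii) the rank-sum phase comparison — so that the full analysis is testable
end to end with no access to patient data.

## The synthetic signal model

No generative model is implied uniquely by published summary statistics, so
the generator makes the weakest set of assumptions that make the analysis
meaningful: the contraction rhythm must be recoverable by a spectral peak,
and amplitudes must scale as observed. Channel 1 (the fundal electrode, the
only one analysed) is

$$V(t) = A\,m(t)\cos(2\pi f_c t + \phi) + b(t) + d(t) + a(t) + \varepsilon(t)$$

* **Slow wave** — a cosine at $f_c = \text{rate}/60$ Hz with amplitude $A$
  and a raised-cosine envelope $m(t) = 1 + 0.5\cos(2\pi (f_c/4) t + \phi_m)$
  (mean 1, depth 0.5 at a quarter of the rhythm frequency). The envelope
  produces the non-stationarity seen in real traces; depth 0 recovers a pure
  tone, which the tests exploit.
* **Bursts** $b(t)$ — band-limited (0.5–5 Hz) unit-variance noise gated
  where the slow wave exceeds its 70th percentile, mimicking spike activity
  riding the depolarising crest. Burst content lies far above the 0.1 Hz
  analysis band, so it perturbs raw traces realistically without carrying
  the phase contrast.
* **Drift** $d(t)$ — one to three random sinusoids below $f_c/4$,
  emulating slow baseline wander.
* **Artifacts** $a(t)$ — fixed tones at 50 Hz (mains), 1.2 Hz (cardiac,
  72 bpm) and 0.25 Hz (respiration, 15 breaths/min).
* **Noise** $\varepsilon(t)$ — white Gaussian sensor noise.

Channels 2–7 are amplitude-attenuated (0.85 per electrode), 2-s-lagged
copies of the deterministic part plus independent noise. This cross-channel
model is deliberately crude — only channel 1 enters the analysis; the other
channels exist so that I/O and channel selection are exercised honestly.

All random draws happen unconditionally in a fixed order and are scaled by
their amplitude parameters afterwards; hence recordings are bit-reproducible
given a seed, and scaling all amplitude parameters by $k$ scales every
sample by $k$ (a tested invariant).

### Phase presets and their calibration

| parameter | PP | LP | why |
|---|---|---|---|
| contraction rate (/min) | 2.4 | 0.4 | observed peak frequencies ~0.04 Hz (PP) vs ~0.0067 Hz (LP) |
| slow-wave amplitude (μV) | 275 | 600 | observed median RMS ~194 μV (PP) vs ~428 μV (LP); $A/\sqrt2 \approx$ RMS |
| burst amplitude (μV) | 80 | 180 | kept proportional to the slow wave |
| rate jitter (log-sd) | 0.15 | 0.15 | across-recording spread wide enough that feature IQRs are non-trivial, narrow enough that phases stay separable |
| amplitude dispersion (log-sd) | 0.25 | 0.25 | log-normal across recordings; a skewed, strictly positive amplitude distribution is the standard biosignal assumption — published summaries give no distribution, so this is a modelling choice, not an inferred fact |
| drift / noise / mains / cardiac / respiration (μV) | 40 / 15 / 10 / 15 / 20 | same | plausible magnitudes for an intrauterine recording with good electrode contact; all are filtered out and mostly sanity-check the preprocessing |

The LP preset rate (0.4/min) lies below the 0.8–6/min physiological range —
deliberately, because observed LP peak frequencies do. Configs flag such
rates (`physiological = FALSE`) instead of rejecting them.

Cohorts default to 11 PP and 15 LP recordings of 10 minutes each (two
5-minute segments per recording, 52 segments). The real study this emulates
mixed 5- and 10-minute recordings, yielding 44 segments (19 PP / 25 LP);
the per-recording durations behind that imbalance are not recoverable, so
the default keeps all durations at 600 s and the segment-count cap does the
rest. Child seeds are spawned from the master seed via `sample.int`,
indexed by recording number.

### What a green test does and does not establish

The generator reproduces the *statistical structure the analysis assumes*:
a dominant low-frequency rhythm whose frequency and amplitude differ by
phase, plus realistic nuisance components. It does **not** model ion
channels, tissue conduction, electrode contact loss, menstruation-phase
cramping, or genuine inter-patient physiology. A passing phase-separation
test therefore establishes that the pipeline correctly recovers the
programmed contrast — not that the contrast exists in real uteri.

## Preprocessing

Per segment, in order (the order is itself part of the protocol):

1. **Segmentation** — sequential non-overlapping 5-minute windows from the
   start of the recording, at most 2 per recording, partial tails dropped.
2. **Mean subtraction** — only voltage *changes* matter.
3. **Lowpass** — 8th-order Butterworth, −3 dB at 0.1 Hz. At the normalized
   cutoff 0.1/256 a direct transfer-function realization is numerically
   unusable, so the filter is designed and run as cascaded second-order
   sections (analytic prototype poles, bilinear transform with
   pre-warping). The magnitude response matches the analytic
   $|H(f)|^2 = 1/(1+(f/f_c)^{16})$ to 1e−6 (tested), i.e. 48.2 dB down at
   0.2 Hz and >200 dB at 50 Hz.
4. **Decimation** — keep every 8th sample: 256 Hz → 32 Hz, 76,800 → 9,600
   samples. The 0.1 Hz lowpass doubles as the anti-aliasing filter; no
   second filter is applied.

**Numerical choices.** The filter is a causal single pass (zero-phase
forward–backward filtering is available as an option but doubles the
effective order, changing the stated magnitude response). Start-up handling
matters more than it first appears: an 8th-order filter at 0.1 Hz settles
over about a minute, and starting it from rest leaks ~4.5% of a broadband
segment's power into the stopband — an order of magnitude above the ≤2%
anti-aliasing budget the pipeline is designed to. Three schemes were
measured on white-noise segments: constant steady-state initialization
(4.5% out-of-band), odd-reflection padding (4.5%; its $2x_1$ mean offset
injects a decaying step), even-reflection padding (1.2%, but its junction
click rings for minutes and defeats pure-tone suppression). The default is
**circular pre-padding**: the filter warms up on the wrapped tail of the
segment (9/cutoff = 90 s, filtered and discarded), which matches the
segment's own spectrum, leaves the transfer function untouched, and drives
the out-of-band fraction to ~0.02% while suppressing a pure 50 Hz tone by
>100 dB. It also pushes the causal output toward the circular convolution
that the downstream periodogram implicitly assumes. `pad = "none"` restores
plain steady-state initialization.

## Features

Per processed segment: $V_{RMS}$, $V_{peak} = \max|V[n]|$,
$V_{pp} = \max V - \min V$ in the time domain; and from the one-sided,
unwindowed full-length periodogram $P(f)$: the peak frequency (argmax), the
power-weighted mean frequency, and the median frequency. The single
full-length transform (no Welch averaging, no taper) gives resolution
$1/300\,\mathrm{s} \approx 0.0033$ Hz, the design figure that sets the
0.198 contractions/min detection limit.

Conventions that require a decision on a discrete grid:

* **Band** — spectral features use $(0, 0.1]$ Hz by default: the DC bin is
  excluded (the mean is removed upstream; excluding numerical residue keeps
  $f_{mean}$ well-defined) and the upper edge equals the filter cutoff so
  stopband residue cannot perturb $f_{mean}$. Full-grid mode is available.
* **Median frequency** — smallest grid frequency where cumulative power
  reaches half the total (left-bin, no interpolation); exact equality of
  the two half-sums essentially never holds on a grid.
* **Peak ties** — broken toward the lowest frequency.
* **Degenerate segments** — zero band power yields `NA` frequency features
  (never 0), excluded from statistics.
* **Scaling** — the periodogram is normalized so that one-sided power sums
  to the mean square of the signal (Parseval, tested at 1e−6 relative;
  spectral features are checked against an $O(N^2)$ direct-DFT oracle at
  1e−9 relative).

## Statistics

Features are compared between phases with the two-sided Wilcoxon rank-sum
test; results are summarised as median (IQR, type-7 quantiles). Exact
p-values (full null distribution of the Mann–Whitney U) are used for
combined $n \le 20$ without ties; otherwise a tie-corrected normal
approximation with continuity correction. At the default cohort size
(≈22 vs 30 segments) the approximate route is taken — both routes are
defensible there, and the switch is exposed (`exact =`). No
multiple-testing correction is applied across the six features, matching
the protocol being replicated.

Each segment is treated as an independent sample even though the two
segments of one recording are correlated. This replicates the original
analysis design and is a known limitation of it, not an endorsement; the
feature table retains `recording_id` so users can aggregate per recording
before testing if they prefer.

## Known limitations

* The generator's contrast is programmed in; effect sizes downstream are
  only as meaningful as the presets.
* Only channel 1 is analysed; the multichannel model is a placeholder and
  unsuitable for propagation studies.
* Published median feature values from real recordings are calibration
  guides only; the package makes no claim to reproduce them, and its
  acceptance checks are phrased as direction + significance, not as value
  matching.
* Recording I/O is CSV + YAML sidecar; EDF is not supported (no suitable
  reader/writer in the supported dependency set).
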