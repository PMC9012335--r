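Package: uemg
Title: Intrauterine Electromyography Simulation and Cycle-Phase Analysis
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing low-frequency intrauterine
    electromyography (uterine EMG) recordings of the non-pregnant uterus. The
    package provides a physiologically motivated synthetic signal generator
    (quasi-periodic contraction slow wave with burst activity, baseline drift,
    mains/cardiac/respiration artifact tones and sensor noise, with presets for
    the proliferative and luteal phases of the menstrual cycle), the standard
    preprocessing chain for such signals (5-minute segmentation, mean removal,
    eighth-order Butterworth lowpass at 0.1 Hz realised as second-order
    sections, x8 decimation to 32 Hz), periodogram-based extraction of three
    amplitude features (RMS, peak and peak-to-peak voltage) and three spectral
    features (peak, mean and median frequency), and a two-sided Wilcoxon
    rank-sum comparison of feature distributions between cycle phases with
    median/IQR summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
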