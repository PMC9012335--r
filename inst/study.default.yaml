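# Default study configuration: reproduces the packaged acceptance runs
# (two-phase simulated cohort, default physiological presets).
n_pp: 11
n_lp: 15
seed: 1
alpha: 0.05
band: [~, 0.1]           # (0, 0.1] Hz: DC excluded, upper edge = filter cutoff
preprocess:
  cutoff_hz: 0.1
  order: 8
  downsample_factor: 8
  segment_duration_s: 300
  max_segments_per_recording: 2
  channel: 1
  zero_phase: false
preset_pp: {}            # overrides for phase_preset("PP"), e.g. duration: 300
preset_lp: {}            # overrides for phase_preset("LP")
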