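# Demo run: synthetic knockdown cohort (traces-only), two conditions,
# 20 cells each (so each group clears the 15-event collection rule), moderate noise.
seed: 42
simulate:
  mode: traces
  design: knockdown
  n_per_condition: 20
  frame_rate_hz: 20
  snr: 10
adhesion:
  window_s: 60
  threshold_um: 10
  assay_s: 420
features:
  k: 3
  m: 5
  ip_mode: raw-ratio
  activation_threshold: 1.5
stats:
  alpha: 0.05
  var_equal: true
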