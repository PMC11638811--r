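# Demo pipeline configuration: a small synthetic lateralized whole-report
# dataset (set-size design) with a forward traveling wave injected on the
# axis contralateral to the memorized side.
template: ds2
simulate:
  n_participants: 3
  n_trials_per_condition: 2
  set_sizes: [1, 6]
  sides: [left, right]
  noise_scale: 1
  noise_exponent: 1
  effect_map:
    - axis: contra
      direction: forward
      amplitude: 0.8
      phase_step: 0.8975979    # 2*pi/7: one spatial cycle across the axis
axes: [midline, left, right]
window:
  length: 0.5
  step: 0.1
bands:
  alpha: [8, 12]
analysis_band: alpha
retention: [0.25, 1.55]
statistic: mean
stats:
  method: quadrature
seed: 42
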