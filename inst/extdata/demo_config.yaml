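# Demo pipeline configuration: default digital pelvis phantom, truth masks
# for generation, continuous-HU mode, full evaluation.
stages: [phantom, segment, sct, drr, eval]
phantom:
  noise_sigma: 0.02
sct:
  mode: continuous
  use_truth_masks: true
  model:
    # bone-distance scale calibrated against the reference CT, analogous to
    # the CT-guided calibration of the clinical HU continua
    d_max: 65
drr:
  axes: [AP, RL]
  mu_water: 0.02
eval:
  cbct:
    enabled: true
    shift_mm: [3.0, -2.5, 5.0]
    noise_sigma_hu: 20
  dose:
    enabled: true
    n_beams: 4
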