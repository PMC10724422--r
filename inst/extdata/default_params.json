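{
  "description": "Calibrated single-cell Ca2+/Na+ model: default kinetic parameters and the standard target-cell stimulus. Produced by scripts/calibrate.R (seed 20231109).",
  "parameters": {
    "V_pump": 0.344468,
    "K_pump": 2.045537,
    "V_cru": 0.554398,
    "K_cru": 1.961317,
    "m_cru": 4,
    "K_h": 1.590098,
    "tau_h": 14.21162,
    "V_ncx": 0.0269488,
    "K_ncx": 0.549508,
    "q_ncx": 2.415711,
    "k_na": 0.000632395
  },
  "stimulus": {
    "t_on": 12.3,
    "duration": 2.717821,
    "intensity": 0.198737,
    "na_coupled": true
  },
  "frames": {
    "frame_interval_s": 1.23,
    "n_baseline_frames": 10,
    "n_post_frames": 121
  }
}
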