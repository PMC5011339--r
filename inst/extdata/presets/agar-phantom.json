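{
  "tissue": {
    "conductivity_W_mK": 0.6,
    "vol_heat_capacity_J_m3K": 4200000,
    "perfusion_s1": 0.02,
    "arterial_dT_C": 0,
    "domain_mm": [12, 12, 12],
    "grid_mm": 0.5
  },
  "source": {
    "focus_center_mm": [0, 0, 0],
    "fwhm_mm": [1.4, 1.4, 10],
    "power_gain_W_per_V2": 84.66,
    "duty": 1
  },
  "scanner": {
    "noise_sigma_phase_rad": 0.14057,
    "drift_rate_rad_per_s": 0,
    "slice_center_mm": 0,
    "slice_thickness_mm": 3,
    "frame_period_s": 3,
    "matrix_dim": [96, 96],
    "fov_mm": [60, 60],
    "te_s": 0.010,
    "b0_T": 4.7,
    "rng_seed": 1,
    "support": "fov"
  }
}
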