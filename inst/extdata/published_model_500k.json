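{
  "a": 6.922,
  "b": 0.988,
  "r2": 0.975,
  "mse": 0.025,
  "n": 14,
  "k": 0.427,
  "n_points": 500000,
  "note": "Published predictive equation for skeletons downsampled to 500000 points: ln(mass_kg) = a + b * ln(alpha_vol_m3) at refinement coefficient k."
}
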