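{
  "mode": "normal",
  "n_structures": 6,
  "pixel_size": 4,
  "tip_fraction": 0.3,
  "opening_radius_um": 30,
  "min_component": 10,
  "seed": 1
}
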