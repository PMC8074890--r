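{
  "preset": "heterogeneous",
  "extents": [100, 64, 64],
  "n_volumes": 1,
  "seed": 1,
  "crop_extents": [400, 200, 200],
  "trim_min_size": 60,
  "target_classes": [3],
  "train_fraction": 0.8,
  "threshold": 0.04,
  "scale": "mini",
  "epochs": 40,
  "batch_size": 32,
  "lr": 0.001,
  "patience": 10
}
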