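{
  "species": "n-butane",
  "n_mol": 4,
  "density": 580,
  "temperatures": [298, 328],
  "n_frames_per_T": 8,
  "stride": 10,
  "tol": 0.05,
  "max_generations": 3,
  "n_bins": 25
}
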