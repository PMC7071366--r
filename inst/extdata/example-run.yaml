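# Example run configuration: scaled-down battery over two conditions.
global_seed: 1
output_dir: results
profile: ci
sets: ["1", "2", "6"]
centers: [ambiguous]
noise_grid: [0.1, 0.5, 1.0, 2.0]
n_networks: 2
n_samples: 20
train:
  samples_per_class: 10
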