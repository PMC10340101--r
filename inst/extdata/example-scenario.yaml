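# Example synthetic-lake scenario: an established mid-density population.
label: example_lake
parent_intensity: 0.125     # substrate patches per m2
mean_offspring: 4           # druses per patch
dispersal_sd: 1.0           # patch scatter, m
cluster_size_law:
  law: ztpois
  mean: 1.2
removal_p: 0.75
distance_p0: 0.8
distance_sigma: 0.4
n_transects: 15
transect_length_m: 30
seed: 1
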