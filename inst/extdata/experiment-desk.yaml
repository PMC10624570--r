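# Desk-scale contour-propagation comparison experiment.
# Load with read_experiment_config() and run with run_experiment().
n_train: 5
n_test: 3
n_fractions: 2
grid_shape: [24, 24, 24]
spacing_mm: [4, 4, 4]
structures: [bladder, rectum, ctv]
methods: [copy, plastimatch_like, BM, PSM, DDFM]
seg_levels: 3
ddf_levels: 3
base_channels: 4
bm_epochs: 45
psm_epochs: 25
ddfm_epochs: 15
ddfm_variant: true_pairs
ptv_margin_mm: 5
rectum_margin_mm: 15
seed: 1
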