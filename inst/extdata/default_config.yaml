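# Default pipeline configuration: a synthetic two-group resting-state
# cohort (130 vs 156 subjects, 90 AAL regions, 950 timepoints at
# TR = 0.5 s) with a connectivity alteration in eight atlas regions.
# Keys are flat with dotted sections; omitted keys keep package defaults.
cohort.n_group_a: 130
cohort.n_group_b: 156
cohort.n_regions: 90
cohort.n_timepoints: 950
cohort.tr_seconds: 0.5
cohort.effect_regions: [33, 40, 59, 69, 70, 77, 78, 90]
cohort.effect_multiplier: 0.85
cohort.subject_jitter_sd: 0.05
cohort.noise_sd: 0.2
cohort.ar1_coefficient: 0.3
cohort.n_modules: 6
cohort.within_weight: 0.4
cohort.between_weight: 0.1
cohort.weight_sd: 0.05
cohort.seed: 1
# Band-pass (0.01-0.08 Hz) before FC; off by default for synthetic data,
# whose spectra are already controlled by the generator.
filter.enabled: false
filter.low_hz: 0.01
filter.high_hz: 0.08
# Stabilization offset: A / (c + sigma_max(A))
controllability.c: 1.0
stats.alpha: 0.05
stats.var_equal: true
classifier_arch.n_hidden_layers: 6
classifier_arch.hidden_width: 64
classifier_arch.dropout_rate: 0.25
classifier_arch.epochs: 200
classifier_arch.batch_size: 32
classifier_arch.learning_rate: 0.001
classifier.k_folds: 10
output_dir: brainctrl_output
master_seed: 1
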