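# brainctrl

Network-controllability analysis of resting-state functional brain
networks in R: from ROI time series to per-region **average
controllability**, region-wise case-control statistics, and a
cross-validated neural-network evaluation of the discriminating regions
as biomarkers.

## The science

Resting-state fMRI yields, per subject, a time series for each atlas
region (here the 90-parcel AAL atlas) and hence a functional
connectivity (FC) matrix of pairwise Pearson correlations. brainctrl
treats that matrix as the wiring of a discrete-time linear
time-invariant system

    x(t+1) = A x(t) + B u(t),

with `A = FC / (c + σ_max(FC))` (largest singular value, `c = 1`), which
makes `A` Schur stable for any input. For input at a single region κ
(`B_κ = e_κ`) the controllability Gramian

    W_κ = Σ_{τ≥0} A^τ B_κ B_κᵀ (Aᵀ)^τ

solves `W = A W Aᵀ + B_κ B_κᵀ`, and region κ's **average
controllability** is `trace(W_κ)` — how cheaply input at κ can steer the
network into nearby states (every value is ≥ 1, the τ = 0 term). The
pipeline then:

1. compares the two groups region by region (pooled two-sample t-test,
   Mann–Whitney U with tie correction, Benjamini–Hochberg FDR across
   regions, top-k rankings of the signed group difference);
2. feeds the significant regions' controllability values to a
   multilayer perceptron (six ReLU hidden layers, dropout 0.25, sigmoid
   output) evaluated with stratified ten-fold cross-validation —
   confusion matrix, accuracy, sensitivity/specificity, per-fold ROC
   and AUC.

Because clinical data of this kind are rarely shareable, the package
includes a seeded synthetic-cohort generator emulating a two-group
study (130 + 156 subjects, 90 regions, 950 timepoints at TR = 0.5 s)
with a connectivity alteration confined to eight designated atlas
regions. See the vignette (`vignettes/controllability-pipeline.Rmd`)
for the generative model and its limits.

## Worked example

A small synthetic study — 20 vs 24 subjects, 30 regions, couplings of
four designated regions weakened by 30% in group B:

```r
library(brainctrl)
cfg <- run_config(
  cohort = cohort_config(n_group_a = 20, n_group_b = 24, n_regions = 30,
                         n_timepoints = 200, effect_regions = c(3, 11, 19, 27),
                         effect_multiplier = 0.7, n_modules = 3, seed = 42),
  arch = mlp_architecture(epochs = 60), k_folds = 5,
  output_dir = file.path(tempdir(), "demo"), master_seed = 42)
report <- run_all(cfg)
print(report)
print(report$comparison)
```

```
Pipeline run: 44 subjects x 30 regions
  significant regions (raw p < alpha): 8; FDR-surviving: 6
  CV pooled accuracy 0.955, mean AUC 1.000
  artifacts under /tmp/RtmpMxIuy5/demo
Region-wise group comparison: 30 regions, n = 20 vs 24, alpha = 0.05
  8 region(s) with p_t < alpha; 6 surviving FDR
 region_id region_name mean_a mean_b     diff t_value       p_t     p_fdr
         3  Region_003  1.116  1.064  0.05184   7.285 5.693e-09 1.708e-07
        11  Region_011  1.096  1.056  0.04000   5.790 7.954e-07 7.954e-06
        19  Region_019  1.087  1.046  0.04130   6.334 1.312e-07 1.967e-06
        21  Region_021  1.102  1.122 -0.02062  -2.392 2.131e-02 8.179e-02
        23  Region_023  1.109  1.130 -0.02151  -2.757 8.595e-03 4.298e-02
        25  Region_025  1.100  1.128 -0.02858  -3.400 1.490e-03 8.940e-03
        26  Region_026  1.096  1.117 -0.02080  -2.382 2.181e-02 8.179e-02
        27  Region_027  1.094  1.062  0.03116   4.549 4.536e-05 3.402e-04
```

All four altered regions (3, 11, 19, 27) surface with positive `diff`
(group A above group B — weakening a region's couplings lowers its
average controllability), and several unaltered regions show small
compensatory shifts in the opposite direction. The classifier separates
the groups nearly perfectly at this effect size; values around 1.05–1.15
are the typical scale of average controllability on stabilized
correlation matrices. The run writes `profiles.tsv`, `comparison.tsv`,
`significant_regions.tsv`, `cv_report.json` and `confusion_matrix.tsv`
under `output_dir`; rerunning with the same `master_seed` reproduces
them byte for byte.

Real data enter through a manifest TSV (`subject_id`, `group_label`,
`path`) referencing either ROI time-series files or precomputed
labelled FC matrices (`ingest_real_manifest()`); band-pass filtering
(zero-phase Butterworth, 0.01–0.08 Hz) is available for raw series. A
command-line driver with subcommands `simulate | fc | control |
compare | classify | run-all` ships at `inst/cli/brainctrl.R`, and a
documented defaults file at `inst/extdata/default_config.yaml`.

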