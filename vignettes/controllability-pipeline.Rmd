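---
title: "Average controllability of functional brain networks: model, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average controllability of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainctrl)
```

## The model

brainctrl treats a subject's resting-state functional connectome as the
wiring of a discrete-time linear time-invariant system

$$x(t+1) = A\,x(t) + B\,u(t),$$

where $x(t)$ is the activity of the $n$ brain regions, $A$ is built from
the region-by-region Pearson correlation matrix of the ROI time series,
and $u(t)$ is an external control signal injected through the input
matrix $B$. For a single input at region $\kappa$ ($B_\kappa = e_\kappa$,
the indicator vector), the controllability Gramian

$$W_\kappa = \sum_{\tau=0}^{\infty} A^\tau B_\kappa B_\kappa^{\mathsf T} (A^{\mathsf T})^\tau$$

is finite whenever $A$ is Schur stable and solves the discrete-time
Lyapunov equation $W = A W A^{\mathsf T} + B_\kappa B_\kappa^{\mathsf T}$.
The **average controllability** of region $\kappa$ is
$\operatorname{trace}(W_\kappa)$ — the established scalar summary of how
cheaply input at that region can push the network into nearby states
(it is the inverse of an average input energy). Because the $\tau = 0$
term contributes $\operatorname{trace}(B_\kappa B_\kappa^{\mathsf T}) = 1$,
every value is at least 1; on stabilized correlation matrices values
land in a narrow band just above 1.

### Stabilization

Raw correlation matrices are not Schur stable, so $A$ is taken as
$\mathrm{FC} / (c + \sigma_{\max})$ with $\sigma_{\max}$ the largest
singular value and $c = 1$ by default. This is the standard convention
of the network-control literature: it guarantees
$\sigma_{\max}(A) = \sigma_{\max}/(c+\sigma_{\max}) < 1$ for any input
while preserving the relative coupling structure. The diagonal of the FC
matrix is zeroed first (self-coupling excluded, the usual connectome
convention), and negative correlations are kept as signed weights by
default — the Gramian formalism accepts signed $A$, and discarding signs
is available as an explicit option (`compute_fc(absolute = TRUE)`)
rather than a silent default. No Fisher z-transform is applied.

### Solving for the Gramian

`node_gramian()` solves the Lyapunov equation by a doubling iteration
($W \leftarrow W + A_j W A_j^{\mathsf T}$, $A_j \leftarrow A_j^2$),
which converges geometrically for any Schur-stable $A$ and reaches
machine precision in a few dozen matrix products; the implementation
reports the Frobenius residual of the Lyapunov defect and the tests
require it below $10^{-8}$. A direct Kronecker-vectorized solve was
considered and rejected: at $n = 90$ it inverts an $8100 \times 8100$
system per node. For the whole-profile computation the package instead
exploits the symmetry of FC matrices: with $A = V \Lambda V^{\mathsf T}$,

$$\operatorname{trace}(W_\kappa) = \sum_i \frac{V_{\kappa i}^2}{1 - \lambda_i^2},$$

so one eigendecomposition per subject yields all 90 regional values.
This closed form makes the $\geq 1$ lower bound exact (each summand is
at least $V_{\kappa i}^2$, and rows of $V$ have unit norm). Both routes
are checked in the tests against the truncated series
$\sum_{\tau < T} A^\tau B_\kappa B_\kappa^{\mathsf T}(A^{\mathsf T})^\tau$
evaluated by repeated multiplication, which is retained as an
independent oracle (`truncated_sum_oracle()`).

The model is deliberately the discrete-time formulation: the Gramian
series above only makes sense for the discrete-time propagator, and it
is the convention under which regional values exceed 1.

## Group comparison

`compare_groups()` performs, per region: group means and their
difference (group A minus group B, the healthy-minus-patient
convention), a pooled-variance Student's two-sample t-test
(df $= n_A + n_B - 2$; Welch available via `var_equal = FALSE`), a
Mann–Whitney U test (midranks, normal approximation with tie and
continuity correction — exact enumeration is unnecessary at group sizes
130/156 and available in tests for $n \le 12$), and Benjamini–Hochberg
FDR adjustment applied across the regions' t-test p-values. All tests
are two-sided. The choice to correct the t-test family (rather than the
U-test family) follows the primacy of the t-test in the comparison;
both raw p-value sets are reported so the reader can adjust either.
`top_k()` ranks regions by signed difference with ties broken by
ascending atlas id.

## Classifier evaluation

Regions with raw $p_t < \alpha$ (default 0.05) provide the feature
matrix, columns in atlas order. The evaluation model is a fully
connected network with six hidden layers of ReLU units, dropout 0.25
after every hidden layer (training only, inverted scaling), and a
sigmoid output giving $P(y = 1 \mid x)$; it is trained with Adam on
binary cross-entropy. Unstated hyper-parameters were fixed once at
conventional values and are configurable: width 64 (a small feature
count needs modest capacity), 200 epochs, batch 32, learning rate
$10^{-3}$. Features are z-scored with training-fold statistics only, so
no information leaks from test folds. Evaluation is stratified ten-fold
cross-validation (plain ten-fold can produce single-class test folds,
which break sensitivity and specificity); the confusion matrix is
thresholded at 0.5, and ROC curves sweep the distinct scores with
trapezoidal AUC, which the tests verify equals the concordant-pair
probability to $10^{-10}$. Both pooled and fold-averaged accuracy are
reported, since either convention is defensible.

One master seed drives fold assignment and per-fold weight
initialization through a splitmix-style integer mix (`mix_seed()`),
making every report reproducible bit for bit.

## What the synthetic cohort emulates — and what it does not

No clinical data ship with the package, so `generate_cohort()` emulates
the target study design: 130 control-like and 156 patient-like
subjects, 90 AAL regions, 950 timepoints at TR = 0.5 s. The generative
model is:

1. a modular ground-truth coupling network (6 modules; couplings ~
   N(0.4, 0.05²) within and N(0.1, 0.05²) between modules, symmetric,
   zero diagonal) — modularity is the dominant large-scale feature of
   real connectomes;
2. a group-B alteration multiplying every coupling incident to eight
   designated atlas regions (ids 33, 40, 59, 69, 70, 77, 78, 90 — the
   mid-cingulate, parahippocampal, superior-parietal, paracentral,
   thalamic and inferior-temporal parcels) by 0.85;
3. per-subject symmetric coupling jitter (sd 0.05) for between-subject
   variability;
4. a positive-definite lift $\Sigma = K + \lambda I$ with $\lambda$
   chosen so the smallest eigenvalue of $\Sigma$ is at least 0.1 — the
   minimal diagonal loading that preserves relative coupling structure
   (correlation-generating models need a valid covariance, which a raw
   coupling matrix is not);
5. rows drawn i.i.d. from $N(0, \Sigma)$, AR(1)-smoothed with
   coefficient 0.3 to mimic BOLD temporal smoothness without modelling
   hemodynamics, plus white measurement noise (sd 0.2).

The alteration multiplier 0.85 is a calibration knob, not an empirical
value: the emulated study reports only group means, not effect sizes on
the couplings. Per-subject seeds are mixed from the master seed, the
group and the subject index, so cohorts are reproducible and
order-independent.

What the generator does **not** emulate: hemodynamic response functions,
head motion and scanner artifacts, spatial (voxel-level) structure,
global-signal fluctuations, age/sex covariates, and the heavy-tailed,
non-stationary aspects of real BOLD. Passing tests therefore demonstrate
that the pipeline's mathematics and statistics behave correctly under a
controlled generative model — calibrated null behavior, correct effect
recovery, chance-level classification without signal — not that the
particular regional differences of any clinical dataset will reproduce.
The injected effect under default settings is in fact considerably
cleaner than clinical reality, where classifier accuracy barely exceeds
chance.

Band-pass filtering (order-2 zero-phase Butterworth, 0.01–0.08 Hz
default band, with demeaning and odd-symmetric edge extension to
suppress filter transients) is applied to real ingested time series;
for synthetic cohorts it is off by default, since the generator already
controls the spectra. Only the band is prescribed by resting-state
convention; the filter family and order are package choices.

## Numerical choices and degenerate inputs

* Lyapunov residual tolerance $10^{-8}$; Gramian PSD tolerance
  $-10^{-10}$ on the smallest eigenvalue; FC symmetry residual
  $10^{-12}$.
* Zero-variance regions abort FC computation with the offending region
  named; series shorter than the filter's padding requirement, bands at
  or above Nyquist, non-square or non-finite adjacencies, single-class
  training data, sub-`k` classes in CV, and mixed or inconsistent
  manifests all fail fast with descriptive errors.
* Ties: midranks in the U test; grouped thresholds in the ROC sweep;
  ascending region id in `top_k()`.
* Problem sizes in the test suite: unit tests run on 12-region cohorts
  of 18–26 subjects; calibration and recovery checks run at the full
  emulated scale (286 × 90 × 950) with three seeds each, which keeps
  the whole suite in the minutes range on a single core.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(cohort = cohort_config(seed = 7), master_seed = 7)
report <- run_all(cfg)
print(report)
print(report$comparison)
plot(report$cv)
```

The pipeline writes `profiles.tsv` (subjects × regions), a
biomarker-style `comparison.tsv` (ID, Name, group means, difference,
p, T, U, FDR), `significant_regions.tsv`, `cv_report.json` and
`confusion_matrix.tsv` under the configured output directory; rerunning
with the same master seed reproduces them byte for byte.
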