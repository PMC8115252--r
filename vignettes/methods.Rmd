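---
title: "Methods: simulated neonatal noxious-evoked response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated neonatal noxious-evoked response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific question

Newborn infants show wide inter-individual variability in the amplitude of
their cerebral haemodynamic (BOLD) response to a mild experimental noxious
stimulus. `neonox` implements, as reusable and testable components, an
analysis chain that asks two questions about that variability: can a
neonate's noxious-evoked response amplitude be predicted from separately
acquired, stimulus-free resting-state activity, and is it coupled to white
matter microstructure (tract-mean diffusivity) in a way that survives an
exploratory–confirmatory two-dataset design?

Because raw neonatal MRI of this kind is not publicly deposited, the package
pairs every analysis stage with a seeded synthetic-data generator whose
ground truth is known. All statistical guarantees quoted in the test suite
are therefore statements about the estimators, verified on data whose
generative law we control — not re-estimates of any empirical result.

## The synthetic cohort model

`cohort_spec()` / `gen_cohort()` implement a linear-Gaussian latent model.
A scalar per-subject *maturity factor* `m ~ N(0, latent_sd²)` drives:

* the true overall evoked amplitude,
  `a = intercept + loading·m + ε`, with defaults
  (intercept 2, loading 1.5, noise SD `1.5·sqrt(1/0.6 − 1) ≈ 1.22`) chosen
  so the amplitude mean (~2), SD (~1.9) and range match a small neonatal
  cohort, and so the *signal fraction*
  `loading²/(loading² + noise²) = 0.6` — the fraction of amplitude variance
  carried by the latent factor;
* nine resting-state network (RSN) amplitudes with positive loadings,
  largest for the somatomotor networks and ~0 for the executive control
  network, plus baseline 2 and noise SD 0.2. The small noise is deliberate:
  network amplitudes estimated by MAD over thousands of frames are highly
  reliable, and the network set as a whole should carry the latent factor
  nearly losslessly so that the designed amplitude signal fraction is also
  the recoverable population R² of the prediction problem;
* 48 tract-mean diffusion features (16 tracts × MD/FA/MK). MD loads
  negatively on `m` (−0.06 for the five designated tracts — anterior and
  superior thalamic radiations, corticospinal tract, forceps minor,
  uncinate fasciculus — and −0.025 elsewhere); FA and MK load positively.
  Each parameter also carries a *shared* maturity-independent factor
  (`tract_shared_sd`, MD default 0.12 against residual noise 0.05). Neonatal
  tract diffusivities are strongly inter-correlated, and this term
  reproduces a designated-tract MD PC1 variance fraction of ~0.85–0.93 while
  keeping the structure–function coupling moderate (population per-tract
  r ≈ −0.3, PC1 r ≈ −0.35 to −0.45);
* confound variables (task/rest framewise displacement, stimulus-correlated
  motion, CSF/WM reference amplitudes, dMRI motion, noisy-voxel count,
  total brain volume) and clinical covariates (gestational, postmenstrual
  and postnatal age, birth weight, brain volume, sex), all with zero
  coupling to `m` by default; scales mirror published neonatal cohort
  descriptives (e.g. brain volume 289 823 ± 49 021 mm³).

The generative law is a convention — no distributional form for the real
quantities is published — chosen because it gives closed-form moments (used
as Monte-Carlo oracles) and makes every recovery target exact.

Image-level generators embed this truth in 4D runs on a phantom grid
(default 24×24×16 at 2 mm in `phantom_geometry()`; the pipeline uses
16×16×12 so the full chain runs in minutes on one CPU): `gen_task_run()`
adds `a_true · group_map(v) · (events ⊛ HRF)(t)` to baseline, per-voxel
random linear drift and AR(1) thermal noise; `gen_rest_run()` mixes network
maps with Gaussian timeseries whose SD is `amplitude/0.6745`, so the
*population MAD* of each network timeseries equals the requested amplitude.
Reference CSF and WM ROIs are placed in the extra-cerebral shell outside
the analysis mask: anatomically CSF surrounds the brain, and the reference
signals must not contain evoked or network signal, otherwise confound
adjustment would remove true signal by construction. The default event
schedule is ten 1 s trials at a minimum 25 s inter-stimulus interval.

What the generator does **not** emulate: spatially structured
physiological noise, motion-correlated signal artefacts, registration
error, non-Gaussian amplitude distributions, or any nonlinearity in the
maturity coupling. Passing tests therefore certify the estimators under
the stated model, not robustness to every property of real data.

## Evoked-response estimation

`double_gamma_hrf()` is the canonical gamma-minus-scaled-gamma kernel,
peak-normalised to 1; the five shape parameters are configurable because
the term-neonate variant's parameters are not printed in the source
literature — the adult canonical values (6/1, 16/1, ratio 1/6) are the
default and the kernel peaks at ~5 s. `build_design()` convolves the event
boxcar on a fine grid (HRF `dt`, default 0.1 s) and samples at acquisition
times; drift is modelled by demeaned polynomial regressors (default order
1) rather than a high-pass filter, and no temporal prewhitening is applied
— the synthetic AR(1) coefficient is kept mild (0.3), and OLS remains
unbiased under serial correlation (only its p-values would be affected,
and all inference here is by permutation).

The *overall response amplitude* is the OLS slope of the subject map
regressed on the group-level map with an intercept (`overall_amplitude()`):
"regressed onto" is resolved so that the group map is the regressor,
giving each subject a scale factor relative to the group response. The
group-level map is the one-sample t-map (`group_tmap()`); zero-variance
voxels yield t = 0 with a warning rather than an error so phantom edges do
not abort runs.

`cluster_inference()` performs one-sample sign-flip permutation inference
with a pseudo-t statistic whose variance map is Gaussian-smoothed (default
FWHM 6 mm) to stabilise low-df inference. Pseudo-t values are converted to
z through their voxelwise permutation-null mid-rank,
`z = Φ⁻¹(1 − (c − 0.5)/B)`; this caps the attainable z at
`Φ⁻¹(1 − 0.5/B)`, so the cluster-forming threshold must be reachable at
the chosen permutation budget (the function default 0.001 needs B ≳ 500;
the pipeline default uses p = 0.01 at B = 500). Clusters use
26-connectivity and voxel count as the cluster statistic; the FWER p of a
cluster is the fraction of permutations whose maximum cluster size reaches
it. Sign patterns are enumerated exhaustively when `2^n` fits the budget
(p-values are then exact multiples of `1/2^n`); otherwise Monte-Carlo with
the `(1+c)/(1+B)` convention. The same exhaustive/Monte-Carlo dual
convention applies to `group_expression_test()` (sign flips of a one-sample
t) and `perm_correlation()` (permutations of one vector).

`effective_tests()` provides both printed-literature estimators of the
effective number of tests — the eigenvalue-partition rule on the absolute
correlation matrix and the eigenvalue-variance rule
`1 + (m−1)(1 − var(λ)/m)` — because which of the two produced the reported
corrected alphas is not stated; the correlation matrix to use is an input.

## Resting-state amplitudes and confounds

Stage-1 dual regression (`spatial_regression_timeseries()`) regresses the
template maps plus a per-frame intercept on every frame; the intercept
absorbs the global level so it cannot leak into network coefficients.
Amplitudes are the unscaled MAD (`mad_amplitude()`, consistency constant
configurable); the outlier metric is the fraction of frames beyond
`k·MAD` (default k = 5, falling back to SD when the MAD is 0) — the source
analysis's exact outlier definition is unpublished, so this is an explicit
stand-in. Template matching across datasets is greedy one-to-one
assignment in descending |spatial r| with a minimum |r| guard of 0.3,
an explicit numeric surrogate for correlation-plus-visual confirmation.

Framewise displacement follows the sum-of-absolute-backward-differences
convention with rotations converted to arc length on a 50 mm sphere
(radius configurable; the upstream tool's exact convention is not
printed). `motion_expansion()` builds the standard 24-regressor set;
`stimulus_correlated_motion()` is the multiple correlation of the
predicted BOLD response with those regressors. ROI amplitudes average the
ROI voxelwise first and then take the MAD of the mean series (the
alternative reading — median of voxelwise MADs — is not implemented as a
mode because the ROI-mean series is the quantity the confound model
needs).

## Prediction

`loocv_svr()` wires together outer leave-one-out cross-validation,
cross-validated confound regression (`cv_confound_regress()`: training-row
coefficients only, residuals applied to train and test rows — the
held-out subject can never influence the adjustment), per-fold feature
z-scoring on training statistics (the source is silent on standardization;
ridge penalties are only scale-comparable across network amplitudes if the
features share a scale), an inner leave-one-out grid search for the
regularisation strength over `{0.001, 0.01, 0.1, 1}` minimising mean
squared error with ties broken toward the smallest C, and a linear
epsilon-insensitive SVR (ε = 0.1). Performance is the sums-of-squares R²
(reported as-is, including negative values), RMSE and Spearman's ρ.
`perm_prediction_test()` shuffles the *raw* response and reruns the entire
pipeline per permutation — confound regression included — so the null
preserves the confound structure; shuffling the adjusted response instead
is available via `shuffle_mode`. `apply_model()` refits once on the full
training sample and scores a new cohort; the target's features are by
default residualized within the target sample (predictors and confounds
extracted in the same manner as in training), with reuse of the training
confound coefficients as the alternative mode.

## Structure–function analysis

Diffusion parameter maps are QC-thresholded to their theoretical ranges
(MD ≥ 0, FA ∈ [0,1], MK ∈ [0,3]) and averaged over tract probability maps
thresholded at 0.01 (`qc_threshold_map()`, `tract_mean()`). The
exploratory screen computes the 48 confound-adjusted Pearson correlations
(partial correlations given dMRI motion, noisy-voxel count and brain
volume) and controls the family-wise error by single-step max-|r|
permutation: each shuffle of the amplitude vector is re-residualized and
re-correlated with all 48 features, and the family maximum forms the
reference distribution. This max-statistic scheme is the package's
concrete choice for the cited-but-unprinted permutation FWER method.

MD pooling (`md_pc1()`) is PCA on column-standardized values — tract MDs
share units but differ in level and spread — with the PC1 sign fixed so
the mean loading is positive (higher score = higher diffusivity), keeping
the hypothesised negative correlation well defined. By default the PCA is
computed on confound-residualized tract values and the PC1–amplitude test
uses the adjusted correlation; the published ordering is unstated, so a
raw-PCA mode exists (`residualize_first = FALSE`). The confirmatory test
is one-tailed in the direction fixed by the exploratory arm, with
permutation p-values; the local cohort drops one subject by
row-completeness filtering, mirroring incomplete dMRI (n = 18 → 17).
`subset_combination_analysis()` evaluates every nonempty subset of the 16
tracts (65,535), computing each subset's PC1–amplitude squared adjusted
correlation through a closed form (top eigenpair of the residualized
correlation matrix), and reports the target subset's inclusive percentile;
"all possible combinations" is read literally (not size-matched), and the
percentile uses ≤.

## Numerical conventions and degenerate inputs

* Monte-Carlo p-values are `(1+c)/(1+B)`; exhaustive p-values are
  `c/total` with the identity permutation included, so the attainable
  minimum is `1/total`. Ties are counted with a `1e-12` tolerance.
* OLS stages go through QR; rank-deficient designs, collinear templates
  and confounds collinear with an input raise errors rather than
  silently pseudo-inverting.
* Zero-variance cases are handled explicitly: t-map voxels → 0 with a
  warning; outlier rule falls back MAD → SD → 0; standardization guards
  zero-SD columns.
* The SVR optimum can have no support vectors under strong
  regularisation; the fit then returns w = 0 with the midrange intercept
  (any intercept keeping all residuals inside the ε-tube is optimal).
* Voxel vectorization is ascending linear (column-major) index order
  throughout, so spatial correlations are order-stable.

## Problem sizes and what the tests show

The test suite and acceptance script run the whole chain at phantom scale:
grid 16×16×12 (analysis mask ≈ 1200 voxels), 260 task volumes (TR 1.3 s,
ten trials), 300 rest volumes, cohorts of 18 (measured) and 215 (tabular,
model-transferred), permutation budgets of 99–600 for calibration studies
and 200–500 inside the pipeline. These sizes were chosen so a complete
run takes minutes on a single CPU while keeping every statistical
property measurable: exhaustive enumerations are exact; null calibrations
use ≥ 300 simulated cohorts with binomial tolerances; recovery checks
compare against closed-form values of the generative model (e.g. the LOO-CV
R² recovery of the 0.6 signal fraction tolerates the ~0.1 small-sample CV
loss inside its ±0.15 band; one-tailed power at a true PC1 correlation of
−0.454 and n = 17 is compared with the Fisher-z analytic value ≈ 0.57).

## Known limitations

* No prewhitening and no mixed-effects group model; group inference is
  permutation-based throughout.
* The rank-based pseudo-t → z transform is granular at small permutation
  budgets (see above); cluster inference at conventional thresholds needs
  B ≳ 500.
* The subset-combination closed form assumes the PC1 eigenvalue is
  positive and unique; exact ties in the correlation matrix (measure-zero
  under the generative model) would make the chosen eigenvector
  arbitrary.
* Clinical covariates are generated uncoupled from the latent factor by
  default, so the package's simulated "clinical variables are not
  predictive" behaviour is an assumption of the default conditions, not a
  finding.
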