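---
title: "Methods: metabolic-pattern and ROI-based classification of dementia FDG-PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic-pattern and ROI-based classification of dementia FDG-PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures implemented, the parameters that matter, the numerical choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not establish about real data.

## The problem

FDG-PET measures regional glucose metabolism, a proxy for synaptic
activity. The common neurodegenerative dementias hypometabolize different
territories — temporoparietal cortex in Alzheimer's disease (AD), occipital
cortex in dementia with Lewy bodies (DLB), frontal cortex in frontotemporal
dementia (FTD) — so a scan carries differential-diagnostic signal. `petdx`
implements an automated four-class (AD / DLB / FTD / normal control)
classification pipeline over two complementary feature sets, plus the
explanation machinery needed to see *which* regions drive each class's
predictions.

## Preprocessing

Volumes are smoothed with an isotropic 3-D Gaussian kernel and scaled to
unit whole-brain mean.

* `fwhm_mm` (default **10 mm**): the conventional kernel for clinical
  FDG-PET group analyses; σ = FWHM / (2√(2 ln 2)) per axis, in voxels
  σ/spacing.
* Convolution is **mask-renormalized**: `conv(data·mask) / conv(mask)`
  inside the mask. Zero-padding would bias edge parcels downward; the
  renormalized form reproduces constants exactly and preserves the masked
  mean of arbitrary volumes to well under 0.5 % (property-tested).
* Global scaling divides by the masked mean ("global uptake"), chosen over a
  cerebellar reference because global normalization is the better-supported
  choice for dementia differential diagnosis; a cerebellar reference is not
  implemented.
* **Order**: the pipeline fixes smooth → scale. Both operations are linear
  in intensity, so the two orders agree up to one overall factor (the tests
  verify they coincide at unit masked mean to 1e-6); fixing one order keeps
  runs bit-reproducible.
* All statistics are computed over the mask only; background voxels are
  never imputed, and a nonpositive masked intensity is an error rather than
  something silently clamped.

## SSM/PCA pattern derivation and TPR scoring

The scaled subprofile model log-transforms the subjects × voxels matrix and
double centers it: each subject's row mean is removed (this is what makes
scores invariant to global intensity scaling), then the column means — the
group mean profile (GMP) — are removed. PCA of the resulting subject
residual profile (SRP) matrix yields covarying topographies.

Design choices, made explicit because the original pattern derivations are
external to this artifact:

* **Candidate components**: the leading components jointly explaining at
  least `var_threshold` (default **0.5**) of SRP variance.
* **Selection**: the single candidate whose subject scores best separate
  disease from controls by two-sample t statistic (default), or an optional
  logistic-regression combination of all candidates (`mode = "logistic"`).
* **Sign convention**: disease derivation group mean score > control mean.
* **Z reference**: the score mean/SD of the control identification cohort
  are stored with the pattern, as is the GMP, so a single prospective scan
  can be scored self-contained: `s = (l − mean(l) − gmp)·w`,
  `z = (s − μ_NC)/σ_NC`.
* **Natural log** (not log10): a base change only rescales scores and is
  absorbed by the Z-transform; fixed for bit-reproducibility.
* The eigen-decomposition is performed in subject space (SVD of the n × p
  SRP matrix), since n ≪ p.

The pipeline derives four patterns: ADRP, DLBRP and FTDRP from each disease
derivation set versus the control identification cohort, and a fourth
"DMN" feature as a *pooled dementia versus control* pattern. The healthy
default-mode pattern proper would be derived from resting-state covariance
in controls alone, which a two-group SSM/PCA cannot produce; the pooled
stand-in fills the same feature slot (a fourth expression score that
separates controls from dementia overall) and is labelled a stand-in
throughout.

## The classifier ensemble

* **Coding**: one-vs-one (K(K−1)/2 binary linear SVMs; the libsvm
  implementation in `e1071` supplies each binary maximum-margin learner).
  Decoding uses the hinge-type loss g(m, f) = max(0, 1 − m·f)/2 averaged
  over each class's learners; the per-class decoded score is the negative
  mean loss. One-vs-all coding is available behind
  `classifier_config(coding = "onevsall")`.
* **Regularization**: C fixed at **1.0**; no tuning is performed, and none
  is reported for the original fitting routine.
* **Standardization**: feature columns are z-scored with *training-split*
  statistics inside every fold (leakage hygiene; config-exposed).
* **Resampling**: 500 stratified 70/30 splits by default. Per class,
  `round(0.7·n)` subjects train (round half to even, the R default),
  adjusted by one only if a class's test set would be empty.
  At 500 iterations every test-eligible subject is expected ~150 test
  appearances.
* **Leakage rule**: subjects used to derive any pattern are forced into
  every training split; they never receive final labels. The "reduced
  dataset" evaluation restricts scoring to the remaining test-eligible
  subjects.
* **Final label**: the modal predicted label over a subject's test
  appearances. Ties are broken by higher vote fraction, then by the fixed
  class order AD < DLB < FTD < NC — the mode needs a deterministic
  tie-break and no other order is canonical.
* **ROC scores**: one-vs-all AUC uses each subject's per-class *vote
  fraction* across iterations. The alternative (mean decoded margin) is
  accessible from the stored models; the vote fraction was chosen because
  it is the quantity the final label is defined on.

## Explanation

* **NCA**: weighted distance d(i,j) = Σ_r w_r²|x_ir − x_jr|; softmax
  reference probabilities over j ≠ i (with the row-minimum distance
  subtracted before exponentiation to guard underflow); objective = mean
  leave-one-out correct-classification probability − λΣw², maximized by
  L-BFGS-B from the all-ones start, converged at projected-gradient
  max-norm ≤ 1e-6 or 400 iterations. The analytic gradient is verified
  against central finite differences (relative error ≤ 1e-4). λ is selected
  on a positive grid by cross-validated 1-nearest-neighbor loss in the
  learned metric, ties to the smaller λ.
* **Selection frequency**: per resampling iteration, features with weight
  above 0.3 × (that iteration's maximum weight) count as selected. The
  relative form adapts the published absolute cutoff (0.3 on standardized
  features) to feature sets whose weight scale varies across iterations.
* **Shapley values**: the explanation target is the ensemble's per-class
  decoded score. For exactly linear scores the closed form
  φ_j = w_j(x_j − E[x_j]) is used; otherwise a permutation-sampling
  estimator (random feature orderings visit coalitions with exactly the
  Shapley kernel weights) with features-not-yet-added imputed from
  background rows, or — in dependent mode — drawn from the Gaussian
  conditional given the features already present (ridge-regularized if the
  background covariance is singular). Each ordering telescopes, so
  efficiency (Σφ = f(x) − E[f]) holds exactly for the independent
  estimator; Monte-Carlo SEs are reported per feature.
* **Budgets**: the background set is the training split of the same
  iteration; explanation defaults to 50 resampling runs with a config
  override (the analysis drivers use 5 runs × 20 subjects × 100 orderings,
  which keeps the Monte-Carlo SE small relative to the planted effects at
  desk-scale runtime).
* **Importance maps**: per class c, the mean over runs and over training
  subjects truly of class c of |φ| for the class-c score, painted onto the
  atlas parcels — absolute values, so the maps show *relevance*, not the
  direction of the effect.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions used throughout the tests and the acceptance script.

| parameter | default | meaning |
|---|---|---|
| `n_per_class` | 63 / 79 / 23 / 41 | AD / DLB / FTD / NC scan counts |
| `grid_shape`, `voxel_size_mm` | 20³, 8 mm | whole-head extent ≈ adult brain |
| `n_rois` | 8 | Voronoi parcels tiling an ellipsoid mask |
| `hypometabolism_fraction` | 0.25 | mean uptake reduction in affected ROIs |
| `variability` | 0.05 | between-subject SD of that reduction |
| `global_scale_sd` | 0.15 | lognormal per-subject global intensity SD |
| `noise_sd` | 0.05 | additive voxel noise SD (baseline is O(1)) |

Each dementia class hypometabolizes two disjoint parcels (AD: 1–2, DLB:
3–4, FTD: 5–6); controls are unaffected. A 20–30 % regional reduction with a
few percent between-subject spread and ~15 % global-scale variation is what
a clinical FDG-PET reader would call a typical, clearly abnormal scan. The
baseline field is a smooth radial gradient (higher centrally) rather than a
constant so smoothing and global scaling interact non-trivially; the global
factor is lognormal so intensities stay positive for the log transform;
noise is added *before* preprocessing and floored at 1e-6.

What the generator does **not** emulate: scanner physics (PSF, attenuation,
partial volume), anatomical-template realism, overlapping or graded
topographies, age/sex covariates, and diagnostic borderline cases. Planted
effects are disjoint across classes, so the synthetic cohorts are close to
fully separable — passing tests demonstrate that the machinery recovers
known ground truth (accuracies near 100 % on clean planted effects), not
that clinical accuracy of any particular level would be reached. The
separability checks are therefore phrased as bounds (≥ 0.9 accuracy,
≥ 0.95 AUC, |r| ≥ 0.8 weight recovery) under fixed seeds.

## Numerical choices and degenerate inputs

* Voronoi parcel ties go to the lower label; parcels are convex ∩ ellipsoid
  and hence connected, and each contains its own site, hence non-empty.
* `double_center` requires ≥ 2 subjects and ≥ 2 voxels; an all-zero SRP
  (no residual variance) aborts pattern derivation.
* A control-score SD of 0 (degenerate Z reference) is an error.
* Metric denominators of 0 yield 0 with a warning (the F1 = 0 convention
  when precision + sensitivity = 0); "other"/inconclusive reader calls form
  a prediction column that can never be correct but counts in totals.
* AUC uses midranks, so ties contribute ½ exactly.
* Singular background covariance in dependent-mode Shapley is
  ridge-regularized with a warning.
* Every stochastic stage (atlas sites, cohort draws, splits, Shapley
  orderings) consumes an explicit seed; per-iteration seeds are derived
  from a master seed, and RNG state is restored afterwards, so whole-run
  outputs are bit-reproducible from the configuration alone.

## Problem sizes

The test suite runs on 12³–16³ grids with cohorts of 24–48 subjects and
25–40 ensemble iterations; the acceptance run and the analysis drivers use
the full default cohort (206 subjects, 20³ grid) with 100–500 iterations
and a 3–5-run Shapley budget. These sizes were chosen so a complete
end-to-end pass is a desk-scale computation on one CPU while every claim
(recovery bounds, invariants, oracle equivalences) is still exercised at
meaningful n.

## Known limitations

* Brain extraction and nonlinear spatial normalization are out of scope;
  volumes must already live on a common grid.
* The real 95/171-ROI anatomical atlases are supported as *inputs* (label
  grid + label table, with composite regions) but not bundled.
* Pattern derivation reimplements a documented default, not the original
  derivations of the published disease patterns (whose component choices
  and thresholds are not public).
* Shapley sampling cost grows linearly in features × subjects × orderings;
  for feature sets in the hundreds, use the `subjects_per_run` cap or the
  linear closed form where applicable.
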