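---
title: "Detecting grid-like codes in abstract 2D navigation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting grid-like codes in abstract 2D navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialgrid)
```

## The model

Population activity of entorhinal grid cells (and, empirically, of
several cortical regions downstream of them) is modulated by movement
direction θ with sixfold angular periodicity. For a region with grid
orientation φ and modulation amplitude ω, the directional component of
the BOLD response to traversing a trajectory is modeled as

$$\mathrm{Activity} = \omega\,\cos\!\big(6(\theta - \varphi)\big)
 = \underbrace{\omega\cos 6\varphi}_{\beta_{\cos}}\cos 6\theta
 + \underbrace{\omega\sin 6\varphi}_{\beta_{\sin}}\sin 6\theta .$$

This identity drives everything in the package:

1. **Detection without knowing φ** (`buildGlm1Design`,
   `quadratureFTest`): regress the signal on $\cos 6\theta$ and
   $\sin 6\theta$ modulators of the morph-stage regressor; the joint
   F test of $\beta_{\cos} = \beta_{\sin} = 0$ is a test of ω = 0 for
   *any* orientation. Per-voxel F is mapped to
   $Z = \Phi^{-1}(P(F' \le F))$, clipped so Z stays finite (default
   |Z| ≤ 8.2).
2. **Orientation estimation** (`estimateOrientation`): ROI-averaged
   betas give $\hat\varphi = \operatorname{atan2}(\bar\beta_{\sin},
   \bar\beta_{\cos})/6$, defined on the fundamental domain [0°, 60°).
3. **Out-of-sample consistency** (`looConsistency`,
   `buildGlm2Design`): with φ estimated from three runs, the held-out
   run's trials are partitioned by their offset from φ into 12 bins of
   30° — six *aligned* (centers 0° mod 60°) and six *misaligned*
   (centers 30° mod 60°) — each bin getting one regressor; the
   contrast is mean(aligned) − mean(misaligned). Each run is held out
   once and the subject-level effect is the mean across runs.
4. **Specificity controls** (`controlPeriodicities`): the identical
   pipeline at folds 4, 5, 7 and 8, with 2f bins of width 360°/(2f). A
   genuine sixfold signal should produce consistency only at f = 6.

The task emulated by the generator navigates a *social value map*: a
unit square whose axes are competence and trustworthiness, both on
[0, 1], with six avatar landmarks. Each recall trial is a trajectory
(direction θ = atan2(Δtrustworthiness, Δcompetence), traveled Euclidean
distance d): 1 s of watched morphing plus an imagination period of the
same duration, followed by a three-option choice. The companion
distance analysis (`buildGlm3Design`) enters d as a parametric
modulator, and the expected-profit rule of the underlying investment
framing, `investment × (1 + competence) × trustworthiness`
(`expectedProfit`), defines the task-relevant distance of the
cooperation comparison block.

## Multivariate route

`lssEstimates` implements least-squares-separate single-trial
estimation: one GLM per trial with a target regressor for that trial's
morph event and a single nuisance regressor for all other morph events
(plus choice, drift, intercept). Two tests consume the patterns:

* *Orientation-independent* (`rsaOrientationIndependent`): Spearman
  correlation between the neural dissimilarity matrix (1 − Pearson
  over trial pairs) and a model DSM in which dissimilarity is the
  angular difference folded by 60°, range [0°, 30°]. Group inference is
  a one-sample t test of Fisher-Z-transformed correlations.
* *Orientation-dependent* (`rsaOrientationDependent`): mean similarity
  among aligned trial pairs minus mean similarity between aligned and
  misaligned pairs, with alignment defined by the same leave-one-run-out
  orientations as the univariate analysis. Pairs are pooled over runs by
  default; `excludeWithinRun = TRUE` restricts to across-run pairs as a
  robustness check (the pooled/restricted choice is left open by the
  source procedures; pooling "all possible pairs" is the default here).

## Circular statistics

Orientations are mapped to the full circle by ψ = 6φ
(`foldTransform`). `vTest(ψ, μ0)` tests clustering around a known mean
direction — used for voxel-wise orientations within an ROI, with μ0 set
to the fold-transformed ROI-mean orientation from the *same* estimating
set, matching the hypothesis that neighboring grid populations share
their orientation. `rayleighTest` tests uniformity of orientations
across participants. Both use standard large-sample approximations
(V: normal approximation of $V\sqrt{2/n}$; Rayleigh: the
$Z = n\bar R^2$ series correction). For n < 10 the analytic
approximations degrade, so the p-value switches to a self-contained
Monte-Carlo null simulation (100 000 uniform samples under a fixed
internal seed, so results stay deterministic); tests verify both
regimes against an independently coded brute-force oracle.

## The synthetic-data generator

The generator is first-class, tested code that emulates the study
conditions end to end:

* **Task schedule** (`sampleRecallBlock`): 80 trials per run, one
  direction drawn uniformly in each of 80 equal bins of [0°, 360°), so
  every bin is occupied exactly once; half of trajectories terminate
  exactly on avatar locations (start back-computed as end −
  d·(cos θ, sin θ), with the admissible d interval derived analytically
  from the unit-square constraint); avatar layouts jittered within
  1/30-unit discs of their centers; morph 2 s (1 s watched + 1 s
  imagined — the watch phase is fixed at 1 s and the imagination period
  matches it, so no per-trial variation is modeled), choice 2.5 s,
  jittered ITI uniform on [2, 6] s. Traveled distance is uniform on
  [0.15, 0.85] map units — the source design did not control this
  distribution, so a wide uniform range was chosen once to give the
  distance modulator healthy variance while keeping trajectories inside
  the map.
* **BOLD model** (`simulateRun`): per voxel, morph-stage neural
  amplitude baseline + ω·cos(f(θ − φ)) (grid voxels), baseline +
  slope·d (distance voxels) or baseline (noise voxels), plus a
  choice-stage response; the event train is convolved with the
  canonical double-gamma HRF (a₁ = 6, b₁ = 1, a₂ = 16, b₂ = 1,
  c = 1/6, unit peak, ~5 s lag) on a 0.1 s grid, sampled at TR = 2 s,
  with additive white Gaussian noise (optional AR(1) via `arCoef`).
  Every generator is a pure function of (config, seed).
* **Behavior** (`simulateBehavior`): explore samples from a mixture of
  avatar-concentrated and uniform components; collect trials with
  angular/positional noise around the ideal trajectory; compare trials
  with log RT = intercept − slope·distance + noise and logistic
  accuracy; recall responses at a set accuracy.

### Calibrated effect size

The default grid-voxel amplitude is **ω = 0.15 with unit noise SD**,
chosen by a one-off pilot so that the per-voxel quadrature Z statistic,
averaged over the four runs, is ≈ 2 — a realistic single-voxel effect
size for this literature. All recovery and power checks run at this
calibration; it is a property of the simulated study conditions, not a
per-test tuning knob.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: directional
tuning shared across an ROI, distance scaling, HRF dynamics, trial
timing, and direction-bin coverage. It does **not** emulate spatial
autocorrelation between voxels, physiological noise spectra, motion,
susceptibility dropout, or inter-regional heterogeneity — so passing
validation demonstrates correctness of the estimators under their own
assumptions, not robustness to every artifact of real acquisitions.
Preprocessing (realignment, distortion correction, normalization,
smoothing) is out of scope; inputs are assumed preprocessed, and the RSA
route assumes unsmoothed data (the pipeline never smooths).

## Numerical and design choices

* **Modulator centering**: parametric modulators are mean-centered per
  run *before* convolution, with no serial orthogonalization — the
  common mass-univariate convention.
* **Drift**: DCT high-pass basis with a 128 s cutoff (configurable;
  `Inf` disables).
* **Estimator**: plain OLS via QR, with an explicit rank check that
  names collinear columns. Degenerate columns (all-zero modulators,
  empty alignment bins) are flagged in the design's provenance table,
  excluded from fitting, and returned as NA betas; alignment contrasts
  renormalize over occupied bins (+1/n_aligned, −1/n_misaligned).
* **Bin edges**: half-open intervals [center − 15°, center + 15°) for
  f = 6, so an offset of exactly 15° belongs to the 30° (misaligned)
  bin.
* **Per-run GLM2**: the consistency GLM is fit per held-out run with
  subject-level averaging of contrasts (rather than on concatenated
  testing sets), keeping the orientation strictly out-of-sample for the
  run it is tested on; a perturbation test asserts this honesty
  property.
* **Group tests**: one-sided one-sample t (align > misalign is a
  directional hypothesis); paired t for fold-6 versus each control
  fold; covariate effects via separate simple regressions with
  Benjamini–Hochberg FDR across covariates. Distance-effect covariate
  indices are per-participant ordinary regression slopes — a
  deterministic, dependency-free stand-in for mixed-model random
  slopes; fitting full mixed models is left to external tooling.
* **tSNR**: σ on the raw series, matching the printed μ/σ definition; a
  `detrend` flag removes a linear trend first for sensitivity analyses.
* **Angles**: degrees at every interface, radians internally.

## Validation studies and problem sizes

The package ships its validation as callable functions, run by the test
suite and `scripts/acceptance.R`:

* `gridCodeStudy()` — 20 subjects × 4 runs × 80 trials, 50 grid voxels,
  φ_true ~ uniform[0°, 60°): median absolute circular error of
  three-run orientation estimates (observed ≪ 5°), group consistency at
  fold 6, and specificity against folds 4/5/7/8.
* `nullCalibrationStudy()` — 100 repetitions of a scaled-down design
  (8 subjects, 2 runs × 20 trials, ω = 0): group-test rejection rate at
  α = 0.05.
* `zCalibrationStudy()` — 2000 null voxels: type-I rate of the
  quadrature Z at α = 0.05 and a KS normality check (under white noise
  the F statistic is exactly F(2, df), so Z is exactly standard
  normal).
* `rsaStudy()` — 20 subjects of generative directional patterns
  (per-voxel gains ~ N(1, 0.3²), tuning cos(6(θ − φ)), unit noise):
  both RSA statistics positive at group level, and centered on zero
  for pure-noise patterns.

These sizes were chosen to give stable Monte-Carlo estimates while
keeping a full validation run in the minutes range on one CPU.

## Known limitations

* Whole-brain cluster-level inference (random-field FWE), searchlight
  mapping, and cross-validated distance estimators (crossnobis) are out
  of scope.
* The AR(1) noise option generates autocorrelated data, but the OLS
  fitter does not prewhiten; with autocorrelated noise, F/Z calibration
  is only approximate.
* ROI handling is index-based (mask files or `sphereRoi`); anatomical
  subdivision atlases are consumed as given masks, never derived.
* The compare-task accuracy slope uses a linear probability fit for the
  exported index; a logistic fit of the same contrast is a one-line
  change via `glm` if preferred.
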