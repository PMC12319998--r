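---
title: "Methods: linking resting-state thought content, connectivity fingerprints, and behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking resting-state thought content, connectivity fingerprints, and behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Resting-state functional connectivity (rsFC) is routinely correlated with
behavioral phenotypes, but during a resting scan subjects are not performing
any task — they are mind-wandering. If people with different behavioral
traits mind-wander differently, and thought content perturbs connectivity,
then self-reported thought content (rsTC) can *account for* part of the
rsFC–behavior association. `mindfc` implements the full statistical chain
needed to test that idea on multi-run resting-state data with post-run
questionnaires:

1. **Fingerprint similarity (H1).** Within each subject, every unique pair
   of valid runs contributes one contrast: the mean absolute difference
   (MAD) of the two runs' FC fingerprint vectors, and the MAD of their
   12-item questionnaire profiles. A random-intercept mixed model
   `MAD_FC ~ MAD_items + (1 | subject)` tests whether similar thought
   content predicts similar connectivity; twelve further models use each
   item's absolute difference individually (one BH-FDR family of 12).
2. **Network correlates (H2).** Each run's node-level FC matrix is
   aggregated into a K×K functional network connectivity (FNC) matrix
   (within-network diagonal included; K(K+1)/2 = 36 unique entries for
   K = 8). One mixed model per (edge, item) pair — 432 models — with
   BH-FDR applied within each item's 36-edge family.
3. **Mediation (H3).** Cross-sectionally, run-concatenated FC gives one
   FNC edge vector per subject and the across-run item means give one
   thought-content profile. For each behavioral phenotype passing a 90%
   completeness gate, two canonical correlation analyses (CCA) against the
   univariate phenotype yield an FNC canonical variate and an item
   canonical variate; a bootstrap mediation then estimates how much of the
   FNC–behavior association (path C) flows through thought content
   (indirect effect A·B, with C = C′ + A·B exactly on any one sample).

## Model and estimation choices

**Mixed models.** `fit_lmm()` fits the random-intercept model by REML via
`lme4`. Inference on the slope uses Wald tests with a normal approximation
(a residual-df *t* is available via `ci_method = "t"`); Satterthwaite or
Kenward–Roger degrees of freedom are deliberately out of scope because at
the group counts this design targets (~164 subjects) the normal
approximation is accurate, which the type-I-error suite verifies directly.
Standardized coefficients are post-hoc rescalings `β·sd(x)/sd(y)` with the
CI endpoints transformed identically, and explained variance is reported as
Nakagawa–Schielzeth marginal and conditional R².

**CCA with a univariate outcome.** With a single variable in the second
set, the first canonical correlation equals the multiple correlation of
the outcome on the predictor set; `cca_univariate_outcome()` computes it
from the whitened cross-covariance (pseudo-inverse whitening with a
warning when the predictor set is rank-deficient) and tests it with the
overall regression F. The canonical variate's sign is fixed so it
correlates positively with the outcome. Scoring: variates are computed by
multiplying column-standardized variables with the *structure loadings*
(`cv_scores(..., mode = "loadings")`), mirroring the analysis convention
this pipeline reproduces; textbook coefficient scoring is available via
`mode = "coefficients"` because loadings-based scoring is non-standard.
Both modes are exercised in the test suite.

**Mediation.** All paths are standardized least-squares coefficients
computed from the correlation closed form, so the identity
C = C′ + A·B holds to machine precision. The indirect effect's 95% CI is
a percentile interval over seeded case-resampling bootstrap replicates
(default 5000); percentile was chosen as the simplest defensible interval
type and is recorded in the result (`ci_type`). Because BH-FDR over
indirect effects needs p-values, a two-sided bootstrap p
(twice the smaller tail fraction of replicates on either side of zero) is
reported alongside the CI.

**FDR families.** `fdr_bh()` wraps the Benjamini–Hochberg step-up
procedure; families are always declared by the caller (12 item-level
fingerprint tests; 36 edge tests per item; one family per canonical
variate across phenotypes; one family of indirect effects). Degenerate
p-values of exactly 0 or 1 pass through unmodified.

## Preprocessing (parcellated stage onward)

The package starts from parcellated node-by-time series; volume-level
steps (realignment, registration, distortion correction) are out of scope.
Denoising follows a fixed order — confound regression, then low-pass
filtering — matching the order this pipeline reproduces; any spectral
reintroduction of noise by that ordering is a property of the reproduced
procedure, not corrected here.

* **Confound regression** takes a design of 6 motion parameters, tissue
  signals (white matter, CSF, global), their first-difference derivatives,
  and a discrete-cosine drift basis (default cutoff period 128 s, the
  field-standard high-pass boundary), removes aliased columns when the set
  is rank-deficient, and replaces every node series by its least-squares
  residual (plus intercept). Residuals are numerically orthogonal to every
  regressor and the operation is idempotent.
* **Low-pass filtering** is a 4th-order Butterworth at 0.1 Hz applied
  forward–backward (zero phase), so no lag asymmetry is introduced into
  cross-correlations. The design requirements (≥ 20 dB attenuation at
  1.5× cutoff, passband flat within 5%) hold with margin for this filter.
* **Motion exclusion** summarizes a run as the mean frame-to-frame RMS
  displacement, rotations converted to arc length at a 50 mm radius — the
  dominant convention when no formula is stated — and excludes runs
  strictly above 0.25 mm; a run at exactly the threshold is retained.

FC matrices are Fisher-z transformed Pearson correlations with
correlations clamped to |r| ≤ 0.999999 first, keeping degenerate synthetic
inputs finite. Fingerprint vectors use a fixed row-major lower-triangle
order with 1-based node indices recorded in an explicit `index_map`, so
vectorization is bit-stable and exactly invertible. Run concatenation
z-scores each node series within run before joining, preventing inter-run
mean/scale offsets from inflating correlations.

## The synthetic-data generator

`generate_dataset()` draws data with exactly the causal structure the
analysis assumes, with every latent recorded in a `ground_truth` object:

* Each subject has a stable Fisher-z **fingerprint**: group-mean edges
  (0.35 within-network, 0.10 between) plus i.i.d. N(0, 0.1²) per-edge
  deviations.
* The **behavioral FC summary** is a declared linear contrast: the mean of
  the between-network block of two nominated networks. Because its
  fingerprint component has a known standard deviation, the latent
  predictor is standardized exactly, making planted paths interpretable as
  standardized coefficients.
* Two latent **thought states** per run: subject state means (the first
  coupled to the FC summary with path *a* = 0.4), plus run-level
  excursions (SD 0.5). The *run-centered* excursions perturb FC edges:
  the vigilance-like state 1 shifts all within-network edges (weight
  0.05 z-units per SD) and state 2 shifts between-network edges outside
  the summary pair more weakly (0.02). Applying state effects to the
  run-centered excursions is a deliberate choice: the run-pair (MAD)
  analyses difference out subject means regardless, while leaving subject
  mean states out of FC keeps the cross-sectional predictor (the FC
  summary) from absorbing the mediator, so mediation recovery is a
  well-posed test. Neither state touches the summary block itself.
* **Questionnaire items** are linear readouts of the states (the
  `vigilance` item is the pure state-1 readout) plus N(0, 0.3²) noise,
  mapped through the normal quantile onto the 0–100 grid and rounded to
  steps of 5 — rank-preserving, and every emitted score lies on the grid.
* **Behavior**: each phenotype is `c′·(FC summary) + b·(subject mean
  state 1) + noise`, residual variance set so the phenotype has unit
  variance and the paths are standardized. Defaults generate a `mediated`
  phenotype (b = 0.4, c′ = 0.3, planted indirect 0.16), a `direct_only`
  phenotype (b = 0) and a `null` phenotype. Missingness is MCAR at 5%;
  only an inclusion threshold is reproduced, so no structured missingness
  mechanism is modeled.
* **Timeseries** are Cholesky-colored AR(1) processes (default
  autocorrelation 0.4, 657 timepoints at 1.4 s): the cheapest stationary
  process whose cross-sectional correlation equals the target exactly,
  since all channels share one temporal filter. Planted targets are
  repaired to the nearest positive-definite correlation matrix by
  eigenvalue clipping (`make_positive_definite()`) — independent edge-wise
  perturbations of a 50-node correlation matrix are otherwise not
  guaranteed positive definite, and a diagonal ridge cannot fix that
  without crushing the planted structure. An `fc_mode = "analytic"` option
  emits per-run Fisher-z FC matrices directly (with edge noise 0.04,
  matching the sampling error of ~650-frame runs) for replicate-heavy
  simulation studies such as power analysis.

One master seed drives subject-level draws and a per-subject-run seed
sequence, so regeneration is bit-identical and partial structures are
reproducible.

**What the generator does not emulate.** Physiological (respiratory,
cardiac) noise, scanner drift and motion artifacts, non-Gaussian BOLD
features, hierarchical network structure beyond a block pattern, and
systematic (non-MCAR) missingness. Passing tests on this generator
therefore demonstrate that the *statistical machinery* is correct and
calibrated under the assumed model — not that real resting-state data
satisfy those assumptions.

## Calibration, recovery, and problem sizes

The test suite fixes the problem sizes as package choices:

* Type-I error of the mixed-model Wald test: 200 null simulations at
  164 subjects × 6 contrasts; the rejection rate must sit inside the
  binomial 95% band around 0.05.
* Bootstrap CI coverage for a planted indirect effect of 0.16 at n = 164:
  200 replicates at the analysis default of 5000 bootstrap resamples,
  compared against the exact binomial band around 0.95. (With only 1000
  resamples the percentile endpoints carry enough quantile-estimation
  noise that coverage drops measurably — one reason the analysis default
  is 5000.)
* BH-FDR control: 500 simulated families of 30 nulls + 6 strong
  alternatives; the mean realized false-discovery proportion must not
  exceed 0.05 beyond Monte-Carlo error.
* End-to-end recovery: 50 full-pipeline replicates at 50 nodes,
  164 subjects, 4 runs detect the planted indirect effect
  (FDR-significant) in at least 90%, while direct-only phenotypes keep
  CIs covering zero. A further 40 analytic-mode replicates check the
  point estimate: it attenuates relative to the planted 0.16 — the
  canonical variates measure the latent predictor and mediator with
  error, and the questionnaire grid adds rounding noise — but stays
  within three replicate standard deviations.

Numerical edge cases are handled explicitly: zero-variance nodes abort FC
computation with the node named; networks with fewer than two nodes have
an undefined within-network entry, flagged and excluded from analyses;
rank-deficient confound or predictor sets are reduced with a warning;
correlation clamping keeps Fisher-z finite; and ties or degenerate
p-values pass through BH unmodified.

## Known limitations

* Wald-normal intervals are mildly anticonservative for very small group
  counts; use `ci_method = "t"` or more subjects in that regime.
* Loadings-based canonical-variate scoring is non-standard; coefficient
  scoring is provided and both are tested, but the default follows the
  reproduced convention.
* The percentile bootstrap can undercover slightly for strongly skewed
  indirect-effect distributions at small n; BCa intervals are out of
  scope.
* Overlapping run-pair contrasts are dependent, and the mixed model does
  not model that dependence; the non-overlapping sensitivity subset
  (`nonoverlapping_subset()`) is the provided remedy, not a covariance
  correction.
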