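---
title: "Methods: PMI estimation from ATR-FTIR biofluid spectra"
author: "pmiftir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMI estimation from ATR-FTIR biofluid spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmiftir)
```

## Overview

`pmiftir` models the postmortem interval (PMI, hours since death) as a
function of the ATR-FTIR absorbance spectrum of a biofluid in the
fingerprint window, 1800–900 cm⁻¹. The analysis has three parts: a
qualitative one — generalized two-dimensional (2D) correlation
spectroscopy, which orders the kinetic changes of individual absorption
bands in postmortem time — and two predictive ones, PLS regression on the
full preprocessed spectra and nu-SVR on a PCA compression of them, each
validated by animal-wise cross-validation, an external animal set, and a
response-permutation test. Because the motivating animal study's raw data
are not available in machine-readable form, a synthetic-spectra generator
reproduces that study's *design* with known ground truth; all package
claims are claims about this generator unless stated otherwise.

## Data model and preprocessing

A `spectra_set` holds an n × p absorbance matrix on a shared, strictly
monotone wavenumber axis (descending by spectroscopy convention; every
operation is orientation-agnostic), with per-sample animal ID, PMI,
replicate index and calibration/validation role. Each animal is sampled at
exactly one PMI — a destructive-sampling design, so "animal" and
"biological replicate" coincide, and instrument replicates (9 by default)
are averaged per animal before analysis.

Two preprocessing steps are used, row-wise and therefore leakage-free:

* **SNV** rescales each spectrum to mean 0, SD 1 across wavenumbers
  (sample SD, denominator n − 1; the choice is immaterial because SNV is
  invariant to positive affine transformations either way, but it is fixed
  and documented for reproducibility). SNV removes additive offsets and
  multiplicative scatter exactly.
* **Savitzky–Golay second derivative** (window 25 points, polynomial
  order 3) sharpens overlapped bands and removes smooth baselines. The
  polynomial order is not dictated by the underlying protocol; order 3 is
  the common chemometric default for second derivatives and is
  configurable. Output length equals input length: at the edges the local
  polynomial is re-evaluated off-center instead of truncating, keeping the
  axis aligned across samples (delegated to `signal::sgolayfilt`, which is
  exact on polynomials up to the configured order — a quadratic a·ν²+b·ν+c
  returns the constant 2a everywhere, including edges). A uniform axis is
  required (relative tolerance 10⁻⁶); irregular grids must be interpolated
  first, which the CSV reader does linearly on the overlap of sample
  grids, never extrapolating.

The default chain for regression is window → SNV → second derivative; the
order is configurable and recorded in the output's provenance attribute.
The 2D correlation branch uses window → SNV only, applied to the
PMI-group averages, since derivative spectra would re-weight the kinetic
amplitudes the method is meant to compare.

## 2D correlation spectroscopy

With group-average spectra y(ν, t₁) … y(ν, t_m) ordered by PMI and
dynamic spectra ỹ = y − ȳ (reference ȳ defaults to the mean over the m
groups, the usual convention when no perturbation-free reference exists;
a supplied reference is accepted), the synchronous and asynchronous maps
are

* Φ = X̃ᵀX̃ / (m − 1) — in-phase covariance; symmetric, non-negative
  diagonal of auto-peaks whose intensity measures each variable's overall
  susceptibility to postmortem change;
* Ψ = X̃ᵀ N X̃ / (m − 1) — out-of-phase component via the Hilbert–Noda
  matrix N_jk = 1/(π(k − j)) (0 on the diagonal); antisymmetric with zero
  diagonal.

Sequential order is read from cross-peak signs: no synchronous peak →
no correlation; synchronous but no asynchronous peak → simultaneous
change; equal signs → the ν₁ change precedes ν₂; opposite signs → it
follows. A sign counts as "no peak" when its magnitude is below ε times
the map's maximum absolute value; ε defaults to 0.01 because published
tables report no explicit threshold — it is a reporting sensitivity, not a
statistical test, and is configurable. Band positions are matched to the
nearest grid point within ±4 cm⁻¹ (a typical instrument resolution);
band lists are user input rather than hard-coded, since reported peak
positions legitimately differ between a band-assignment table and the 2D
maps' extrema. Auto-peak ranking uses plateau-aware local maxima of
diag(Φ): when a band center falls midway between grid points the two tied
samples form a run, which is treated as one peak at its middle index.

## Regression models

**PLS (NIPALS).** Univariate-response NIPALS with X-only deflation and
per-factor recomputed response loadings; weight vectors are unit-norm
with the first non-negligible element forced positive, making the fit
deterministic and permutation-invariant. Seven latent factors is the
reference setting. At full rank PLS reproduces ordinary least squares
(used as an independent oracle in the tests); if the data's rank is
exhausted earlier, extraction truncates with a warning. Variable
importance in projection uses SS_a = q_a²·t_aᵀt_a as the per-factor
response variance, so ΣVIP² = p identically, and VIP > 1.0 (strict)
flags influential variables.

**nu-SVR.** RBF-kernel nu-SVR via libsvm (`e1071`), nu = 0.02 in the
reference setting: nu bounds the margin-error fraction from above and
the support-vector fraction from below, so predictions are a kernel
expansion over support vectors only (verified against an explicit dual
reconstruction in the tests). Inputs are first compressed to 8 principal
components — fitted on training rows only and reused unchanged for any
prediction, which the tests verify explicitly — because the RBF kernel
gains nothing from hundreds of collinear derivative channels. Note the
libsvm convention: `cost` bounds each per-sample dual coefficient, so
duplicating the training set is equivalent to doubling `cost`, not a
no-op. Cost and gamma come from an exhaustive 2D grid search over the
standard log₂ lattices cost ∈ 2^{−5,−3,…,15}, gamma ∈ 2^{−15,…,3}
(configurable; the reference protocol shows a grid search but not its
ranges), minimizing cross-validated RMSE over the same animal-wise folds
used everywhere else, with ties broken toward smaller cost then smaller
gamma. The PCA projection is refitted inside each training fold; since it
does not depend on (cost, gamma), it is computed once per fold, not per
cell.

## Validation

**Cross-validation** is animal-wise and stratified: the calibration
animals of each PMI group are spread evenly over k folds (k = 8 in the
reference design, giving folds of 9 spectra covering all 9 PMI groups —
one animal per group per fold). Per fold, the model (including any PCA
step) is refitted on the remaining folds and the held-out fold predicted;
R² and RMSECV are reported as mean ± SD over folds, the most direct
reading of "assessed each time" protocols (repeated CV is a possible
alternative reading; it is not implemented). Degenerate comparisons in
the Welch t-based model comparison (both fold vectors constant) are
handled as limits: equal means give t = 0, p = 1, unequal means p → 0.

**External validation** predicts the validation animals with the
calibration-fitted model and reports Q² (determination coefficient of
those predictions, using the validation-set mean) and RMSEP. With a
single validation sample Q² is undefined and returned as `NA` with a
warning while RMSEP is still reported.

**Permutation test.** The response is randomly permuted n_perm = 50
times; the model is refit each time with hyperparameters frozen (same
factor count, nu, cost, gamma — re-running the grid search under
permutation would answer a different question). For each permutation we
record the training R² of the refit and a cross-validated Q² (pooled
held-out predictions over the fixed animal-wise folds; an external-set
option exists because protocols differ on this point), plus the absolute
correlation of the permuted response with the original. Straight lines
of R² and Q² versus correlation, fitted through the permuted points and
the unpermuted point at correlation 1, give the intercept criterion: a
sound model has its original R² and Q² above every permuted value and a
Q² intercept at or below zero. R² here is goodness of *fit* and Q² the
cross-validated metric — the standard reading of such validation plots,
in which the R² intercept is typically small but positive while the Q²
intercept is negative; a cross-validated R² would be negative under
permutation and could not reproduce that pattern.

## The synthetic-data generator

The generator emulates the reference study design: PMI groups at
0, 6, …, 48 h; 11 animals per group, randomly split 8 calibration / 3
validation; 9 instrument replicates averaged per animal; axis 1800–900
cm⁻¹. The point spacing is 2 cm⁻¹ — the underlying protocol states a
4 cm⁻¹ instrument resolution but not the digitized spacing, so 2 cm⁻¹ is
a typical interferogram-interpolated value and configurable.

Each spectrum is a sum of Gaussian bands (Gaussian rather than
Voigt/Lorentzian: analytically convenient and sufficient for testing
band-resolved kinetics) at canonical biofluid positions — amide I 1650,
amide II 1540, C–H bending 1453, COO⁻ 1398, amide III 1324, phosphate /
saccharide 1078, glucose 1033, carbohydrate 926 cm⁻¹ — plus a protein
band at 1581 cm⁻¹ that published 2D analyses of postmortem biofluids
resolve as a strong late-stage auto-peak. Band amplitudes follow sigmoid
kinetics b + δ/(1 + e^{−r(t − t₀)}): early onset (t₀ = 6 h) for the
amide I/II/III bands, emulating protein infiltration and early
degradation; late onset (t₀ = 30 h) for the 1581 and 1078 cm⁻¹ bands,
emulating glycoprotein leakage after barrier collapse; constant
elsewhere. The largest amplitude change sits on amide I so the amide
region dominates the synchronous diagonal.

Per replicate, the band sum is perturbed by a random quadratic baseline,
multiplicative scatter (random slope on the signal plus additive offset —
exactly the affine disturbance SNV removes), and white noise; each animal
carries one multiplicative random effect. Defaults (additive SD 0.004
a.u., scatter slope SD 0.05, offset SD 0.02, baseline coefficient SD
0.01, animal effect SD 0.04) were chosen once so that the pipeline's
cross-validated R² lands in the 0.95–0.99 regime typical of well-run
FTIR time-course studies — they are a calibration of the scenario, not
values derived from any instrument. The generator does **not** emulate
water-vapor lines, Mie scatter, detector nonlinearity, inter-animal
kinetic heterogeneity (onsets are shared; only amplitudes vary by
animal), or real biochemical complexity; passing tests therefore show
that the *pipeline* recovers known structure under realistic noise, not
that any real biofluid behaves this simply.

## Numerical choices and degenerate inputs

* SNV errors on flat spectra; the preprocessing chain reports the
  offending sample.
* NIPALS stops extraction when the weight or score norm falls below
  10⁻¹² of the problem scale (warning + truncation); zero-variance
  responses are rejected.
* Grid-search ties break toward smaller cost, then smaller gamma, so the
  argmin is unique and deterministic.
* Fold assignment, simulation, grid-search folds and permutations all
  derive their seeds from one master seed; pipeline reruns are
  byte-identical.
* Problem sizes in the tests follow the reference design (99 animals,
  9 groups, 8-fold CV, 50 permutations) for the end-to-end checks, with
  smaller seeded scenarios (e.g. 5 groups × 4 animals, 3 replicates,
  4 cm⁻¹ spacing) for per-module properties — chosen as the smallest
  designs that still exercise the stratified fold structure.

## Known limitations

* Only univariate responses (PMI) are supported in PLS; no automatic
  factor-count selection (7 and 8 are the reference settings and
  configurable, not optimized).
* The 2D module implements homo-spectral, unscaled maps; moving-window
  and hetero-spectral variants are out of scope.
* Q² conventions differ across the literature (validation-set mean vs
  training mean in the denominator); this package uses the
  validation-set mean, i.e. plain R² on the external predictions.
* The permutation test freezes hyperparameters; it does not account for
  selection effects of the grid search itself.
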