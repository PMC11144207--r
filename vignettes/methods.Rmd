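---
title: "Functional-lung dosimetry from breathing deformations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-lung dosimetry from breathing deformations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventidose)
```

## The problem

Thoracic radiotherapy planning traditionally constrains physical lung dose
metrics such as V20 and V30 — the percent of lung volume receiving at least
20 or 30 Gy — yet radiation pneumonitis (RP) of grade 2 or higher still
occurs at substantial rates. Lung function is regionally heterogeneous, so
the same physical dose can injure very different amounts of *functioning*
lung. Respiration-correlated CT (4D-CT) offers a cheap, high-resolution
surrogate for regional ventilation: registering two breathing phases yields
a displacement field whose local volume change tells how much each tissue
element inflates.

`ventidose` implements that chain end to end: deformation → Jacobian
ventilation map → high-function lung (fLung) segmentation → functional
dose-volume covariates (V5…V60 of fLung) → logistic risk models for
grade-≥2 RP, screened by four variable-selection strategies and evaluated
by ROC, optimism-corrected calibration and nomogram. Because clinical
4D-CT cohorts are private, the package also ships a synthetic phantom and
cohort generator with analytically known ground truth, so every stage is
testable.

## Deformation and the Jacobian ventilation surrogate

A displacement field $u(x)$ on the fixed grid maps each voxel centre $x$
(world mm) to its corresponding location $x + u(x)$ in the other breathing
phase. The local volume-change ratio is the Jacobian determinant of the
deformation $\varphi(x) = x + u(x)$:

$$ J(x) = \det\!\left(I + \frac{\partial u}{\partial x}\right). $$

$J > 1$ marks local expansion (inhaled air), $J < 1$ compression, and
$J \le 0$ grid folding (retained, counted, and reported, but never part of
fLung at positive thresholds). Derivatives use spacing-aware central
differences in the grid interior and one-sided differences at borders;
central differences are *exact* for affine fields, which provides the
closed-form test $u = a\,x \Rightarrow J = (1+a)^3$.

The high-function lung is a strict threshold on the raw map:
$\text{fLung} = \{x \in \text{lung} : J(x) > 1.2\}$. The 1.2 cut is the
field's convention for "high-function" ventilation on the raw Jacobian; no
normalisation by mean lung $J$ is applied, and no pre-smoothing is done by
default (an optional Gaussian flag exists but is off — threshold stability
under smoothing was judged a user decision, not a silent default).

## Registration

The deformable registration producing $u$ is pluggable: precomputed fields
can be read from NIfTI or MetaImage, and the package ships a
multi-resolution diffusive demons implementation as the reference source.
Each iteration computes the Thirion force
$v = (F - M_w)\,\nabla M_w / (\lVert\nabla M_w\rVert^2 + (F - M_w)^2/s^2)$
(with $s$ the mean voxel spacing stabilising the denominator's units),
adds it to the field, and smooths each component with a Gaussian of
standard deviation `smoothing_sigma_mm`. Levels run coarse to fine
(downsampling by two per level after Gaussian pre-filtering), warm-starting
the field by trilinear upsampling.

Numerical choices worth knowing:

* **Fixed iteration budgets, no convergence test** — determinism was
  preferred over adaptive stopping; reruns are bit-identical.
* **A final safety check** compares the mean squared intensity difference
  against the zero field and falls back to zero (with a warning) if
  registration diverged; constant-intensity inputs short-circuit to a zero
  field because the problem has no gradient.
* **Smoothing sigma trades accuracy against Jacobian contrast**: heavy
  smoothing (≥ 5 mm) yields low displacement error but flattens $J$ toward
  1, shrinking fLung; the analysis scripts use 3 mm with 200 iterations
  per level, which on the bundled phantom recovers the truth fLung
  fraction to within about one percentage point. Too little smoothing
  (≤ 2 mm here) destabilises the update and triggers the zero-field
  fallback.

## The synthetic phantom

The phantom emulates one breathing excursion with a field whose Jacobian
is known in closed form: $u = (0, 0, u_z)$,

$$ u_z = A\,\sin^2(\pi t_x)\,\sin^2(\pi t_y)\,
   \frac{\sin(\pi s)e^{-\lambda s}}{g_{\max}}, $$

with $t_x, t_y, s \in [0,1]$ the normalised grid coordinates, $A$ the peak
craniocaudal displacement (mm) and $\lambda$ the decay toward the apex
($s = 1$). Because only $\partial u_z/\partial z$ enters the determinant,
$J = 1 + \partial u_z / \partial z$ exactly. The sine-squared tapers make
the field $C^1$ and zero (with zero slope) at the lateral borders. An
affine mode ($u = a(x - x_c)$, $J \equiv (1+a)^3$) provides the standard
closed-form oracle.

The exhale intensity model is a smooth analytic pattern — a soft-tissue
body envelope, two air-like ellipsoidal lungs, and low-frequency internal
texture so registration has gradients to work with. The inhale volume is
the exhale resampled through the analytic field with trilinear
interpolation, which makes "warping exhale by the truth reproduces inhale"
an exact identity and isolates interpolation error elsewhere.

Parameter defaults: 10 mm amplitude and decay 1.5 for the generic
`phantom_spec()` (free-breathing scale); the analysis scripts use 25 mm —
a deep-breathing diaphragm excursion — because on their 19 cm grid extent
that produces regional $J$ up to ≈ 1.4 at the lung base, the regime where
a 1.2 threshold actually carves out a minority high-function subvolume.
Intensities are HU-like but arbitrary; nothing downstream interprets
absolute values. What the phantom deliberately does **not** emulate:
realistic CT texture and noise spectra, 10-phase cine reconstruction,
breathing irregularity and sorting artifacts, or sliding motion at the
pleura. Tests passing on the phantom certify the *numerics* (warping,
Jacobians, DVH accounting), not robustness to clinical image artifacts.

The Gaussian dose model ($D = D_0 e^{-r^2/2\sigma^2}$, peak at the target,
$\sigma$ = `falloff_mm`) is likewise an analytic stand-in for a planned
distribution, chosen because its integral and level sets are closed-form.

## Functional dose-volume accounting

DVH computation is deliberately the simplest defensible convention: voxel
counting with uniform voxel volume, $V_x = 100 \cdot |\{v \in \text{mask}:
D(v) \ge x\}| / |\text{mask}|$, inclusive at the level. Dose on a
different grid is resampled to the *mask's* grid by trilinear
interpolation (never the mask to the dose grid, which would corrupt
topology). $V_x$ is relative (percent of fLung) — the convention under
which the published model's coefficients act and the one clinical V20/V30
constraints use; absolute cc output is available behind a flag. No
partial-volume weighting is applied: determinism and exact brute-force
testability were valued over sub-voxel accuracy, and the
resolution-doubling test bounds the residual discretisation error at under
one volume-percent on edge-aligned grids at 4 mm.

## Cohort simulation

The simulated cohort reproduces the *statistical regime* of the emulated
study rather than its (unavailable) raw data:

* $n = 41$ patients, twelve covariates V5…V60 in percent.
* Covariates drawn multivariate normal with an AR(1) correlation
  $\rho^{|j-k|}$, $\rho = 0.92$, per-level SD 9 — adjacent dose levels are
  nearly collinear, the regime in which stepwise, best-subset, lasso and
  random-forest screening genuinely disagree.
* Each draw is sorted decreasing and clipped to $[0, 100]$, so every
  simulated patient has a valid cumulative DVH ($V_5 \ge V_{10} \ge \dots
  \ge V_{60}$).
* Outcomes are Bernoulli with logit from the published stepwise
  coefficients; the simulation intercept (−0.898) was calibrated once, by
  root-finding at large n, so the expected event rate equals the study's
  16/41. It is deliberately *not* the published intercept: the generating
  model is a design choice that fixes the event rate, not an estimate.
* The mean profile (62, 52, …, 4 percent) is a plausible decreasing fLung
  DVH; the emulated study never reports its covariate distribution, so
  these are free, documented choices — not estimates of that population.

## Risk modelling

`fit_logistic()` is binomial maximum likelihood via IRLS (`stats::glm`
machinery) with two extra guarantees: the score equations
$X^\top(y - p)$ are verified at the solution, and quasi-complete
separation — any coefficient beyond 15 on the standardised scale — is an
error naming the covariate rather than a silently absurd estimate.

The four selectors mirror the standard toolbox:

* **Stepwise (bidirectional, AIC)** starts from the *full* 12-covariate
  model and applies the single add/drop that most reduces AIC until no
  move helps. Ties break toward fewer variables, then covariate order
  V5 < V10 < … < V60. The result is asserted to be a local optimum.
* **Best subset (exhaustive, AIC)** fits all $2^{12} = 4096$ subsets;
  non-convergent subsets are skipped with a warning and can never win.
  AIC was chosen as the criterion (rather than BIC or CV) so that the two
  regression selectors optimise the same objective and their agreement —
  the emulated study's headline finding — is a meaningful check rather
  than an artefact of mismatched criteria.
* **Lasso** is an in-package coordinate-descent solver for
  $-\tfrac1n \ell(\beta_0, \beta) + \lambda\lVert\beta\rVert_1$ on
  standardised covariates, warm-started along a log-spaced path from
  $\lambda_{\max} = \max_j |x_j^\top(y - \bar y)|/n$ (where the zero
  vector is analytically optimal — enforced exactly, not numerically)
  down to $10^{-4}\lambda_{\max}$. Karush–Kuhn–Tucker residuals of the
  exact binomial objective are computed at every path point; the tests
  hold them below $10^{-6}$, and the path is cross-checked against an
  independent solver. $\lambda$ is chosen by 10-fold cross-validated
  deviance with a seeded fold assignment; the reported model keeps the
  *penalised* (shrunken) coefficients at that $\lambda$, matching how
  lasso formulas are conventionally published.
* **Random-forest importance** wraps the canonical bagged-CART
  implementation (Gini splitting, $\sqrt{p}$ feature subsets), reporting
  unscaled out-of-bag permutation importance and total Gini decrease with
  descending rankings. It ranks; it does not return a logistic model.

The published formulas ship as constants (`published_stepwise_model()`,
`published_lasso_model()`) and are interpreted as **linear predictors on
the logit scale** — they come from binomial GLM fits, so "Risk" passes
through the sigmoid to become a probability. Covariates enter in percent.
Their coefficients cannot be re-estimated here (the source cohort is
private); they are evaluated, scored, and turned into nomograms as worked
examples.

## Evaluation

* **ROC/AUC**: Mann–Whitney concordance with ties counting ½, equal to
  the trapezoidal area; verified exactly against brute-force pairwise
  comparison on small instances.
* **DeLong interval**: placement-value variance with a normal
  approximation truncated to $[0,1]$, collapsing to a point interval
  (with a warning) under perfect separation. Coverage is simulation-tested
  against a binormal ground truth. DeLong was chosen because the emulated
  study's printed interval is symmetric about its AUC, consistent with a
  normal-approximation method; the study itself does not name one.
* **Calibration**: the optimism-bootstrap convention — apparent curve from
  a locally smoothed observed-vs-predicted fit on a fixed
  predicted-probability grid; per-replicate optimism = (replicate-model
  calibration on the replicate) − (replicate-model calibration on the
  original data); bias-corrected curve = apparent − mean optimism.
  The corrected calibration slope equals the mean recalibration slope of
  replicate models on the original data (apparent slope is 1 by
  construction). Single-class resamples are redrawn and counted. Grouped
  predictions (≤ 10 distinct values) use exact group frequencies instead
  of smoothing, so saturated models calibrate exactly.
* **Nomogram**: points$(x_j) = 100\,|\beta_j|(x_j - \text{ref}_j) /
  \max_k |\beta_k|\,\text{range}_k$ with the reference at the end of the
  range minimising $\beta_j x_j$, so points are non-negative and the
  dominant covariate spans exactly 0–100; total points map back to risk
  through the linear predictor. With the published coefficients and equal
  0–100 ranges the dominant variable is V25 — determined by
  $|\beta|\cdot$range, so which covariate "matters most" in a clinical
  nomogram depends on the cohort's actual covariate ranges, which the
  emulated study does not print.
* **Contingency comparisons**: Pearson chi-square without continuity
  correction, the convention that reproduces the printed machine-type
  (p = 0.707) and fractionation-class (p = 0.929) comparisons exactly from
  their printed counts. The other printed cohort-table p-values (sex,
  tumour location, age, volume) are not reproducible from printed
  information under standard tests and are not asserted anywhere.

## Problem sizes

The test suite and analysis scripts run on sizes chosen for thorough
coverage at interactive speed: phantoms of $16^3$–$48^3$ voxels,
registration at 3 levels × 50–200 iterations, cohorts of 41–2000 patients,
full $2^{12}$ best-subset enumerations at n ≤ 300, 1000-replicate DeLong
coverage at 200 + 200 scores, and 100–1000 bootstrap calibrations. These
reproduce every qualitative regime of the method (collinear selectors,
optimism under overfitting, Jacobian contrast under smoothing) without
requiring clinical-scale $512^2 \times 100$ volumes, which the
implementation handles by the same code paths but is not routinely
exercised on.

## Known limitations

* The demons implementation is diffusive, not diffeomorphic: large or
  sliding deformations can fold (reported via the non-positive-Jacobian
  count), and the pleural sliding of real lungs is not modelled.
* Voxel-counting DVH ignores partial volumes; at coarse grids the
  discretisation error is the dominant uncertainty in $V_x$.
* The random-forest stage inherits the instability of importance rankings
  at n = 41 — the emulated study's forest-specific figures are
  acknowledged as irreproducible, and no test asserts a particular
  clinical ranking.
* The cohort generator produces plausible but synthetic covariate
  distributions; conclusions about *selector behaviour* transfer,
  numerical coefficient values do not.
* Phase-pair registration uses the two extreme phases as a single pair;
  composing adjacent-phase fields across ten phases is noted but not
  implemented, as the source workflow's composition rule is ambiguous.
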