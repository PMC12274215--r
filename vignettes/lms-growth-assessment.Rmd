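---
title: "LMS growth assessment: model, numerical choices and verification design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LMS growth assessment: model, numerical choices and verification design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrowth)
```

## The LMS model and its two transformation modes

A growth reference in LMS form summarises the age-conditional distribution
of a measurement by three curves: the Box-Cox power L(t), the median M(t),
and the scale S(t). `agrowth` evaluates a measurement X at age t in two
modes, dispatched per parameter:

* **Identity mode** — `Z = (X − M)/S`. The seven parameters whose source
  charts tabulate L = 1 everywhere (height, head circumference, sitting
  height, leg length, arm span, relative sitting height, foot length) use
  this plain standardisation. In this mode S is an **absolute standard
  deviation in measurement units**, not a coefficient of variation.
* **Box-Cox mode** — Cole's form `Z = ((X/M)^L − 1)/(L·S)`, for the
  right-skewed parameters weight and BMI. Here S is a **coefficient of
  variation** (dimensionless) and L is typically negative.

The coexistence of two S conventions in one bundle is a real property of
the source charts, and an easy silent failure: supplying a CV where an SD
is expected deflates every z-score by an order of magnitude. The validator
therefore emits a warning-severity record when an identity-mode node has
S < 0.5 while M > 20 — a combination essentially impossible for an SD of a
body measurement but typical of a CV. It is a warning, not an error,
because small-magnitude parameters can legitimately have sub-0.5 SDs.

A well-known precedence trap in typeset LMS formulas is whether the
Box-Cox denominator is `L·S` or `L` followed by multiplication with `S`.
Only division by the product `L·S` yields a standard-deviation score (it is
the first-order Taylor coefficient of the transform), and it is the form
under which the L→0 limit `ln(X/M)/S` is continuous; `agrowth` implements
that canonical form.

### The log-limit branch

At L = 0 the Box-Cox transform degenerates to `ln(X/M)/S` analytically,
and near L = 0 the literal formula suffers catastrophic cancellation:
`(X/M)^L − 1` is O(L) and the division by L amplifies rounding error. The
engine switches to the log branch when |L| < 1e-7. The relative error of
the limit as an approximation is O(L), so at the threshold both branches
agree to about 1e-7 — the crossover is seamless at double precision, which
the continuity tests check at ε ∈ {1e-4, 1e-6}.

### Percentiles and inversion

Percentile = 100·Φ(Z) via `stats::pnorm`, inverted with `stats::qnorm`;
both are standard-library calls, and the test suite cross-checks `pnorm`
against adaptive quadrature of the normal density (`stats::integrate`,
rel.tol 1e-12) on z ∈ [−6, 6] at 1e-7, so the conversion is verified
rather than assumed. Percentiles are computed and stored at full floating
precision; only the CLI rounds for display (2 decimals for z, 1 for
percentiles), matching chart-reading granularity. Reported percentiles are
not truncated to a chart range such as 0.1–99.9: an extreme value prints
as the extreme percentile it is, flagged `extreme_percentile` when
|z| > 3. The threshold 3 is an informational convention — it marks scores
beyond the outermost centile line of a printed chart (99.87th), where a
clinician should double-check the entry — and has no computational effect.

The inverse transform `X = M·(1 + L·S·z)^(1/L)` exists only while
`1 + L·S·z > 0`; outside that support the engine raises an invertibility
error rather than returning a complex or clamped value. This matters for
synthetic data generation at extreme z (see below).

## Age interpolation

Reference grids tabulate coefficients at discrete ages; patients present at
arbitrary ones. `agrowth` interpolates **coefficients, not z-scores**:
L, M and S are each linearly interpolated in age between the two bracketing
nodes, and the transform is applied once at the interpolated triplet. The
alternative — scoring at both nodes and interpolating z — is not
equivalent for Box-Cox parameters (z is nonlinear in the coefficients) and
is not how LMS references are conventionally used.

Linear interpolation was chosen over cubic or spline schemes because it is
exact at the nodes, bounded by the bracketing values, monotone between
nodes, and has no tuning parameters; on 6-month/annual pediatric grids the
curvature of L, M, S between nodes is small relative to measurement error.
The choice is documented precisely so users can quantify the difference
against a spline alternative if their bundle is coarse.

Age domains are **closed** intervals: the endpoints (birth, 20 years; 2 or
3 years for the proportion parameters) are valid query ages, and anything
outside raises an out-of-domain error carrying the valid range. Silent
clamping was rejected because an out-of-range age is clinically meaningful
(wrong chart, typo in dates) and must surface. When dates rather than a
decimal age are supplied, age = (visit − birth) in days / 365.25.

## The synthetic reference generator

The coefficients of the published European achondroplasia charts are
licensed publications and are not shipped; the generator
(`generate_reference()`) produces structurally faithful stand-ins:

* **Grid layout**: 6-month nodes from birth to 4 years then annual nodes
  to 20 for height, weight, BMI and head circumference (25 nodes; age 4.0
  appears once, as both the last half-year node and the first annual one);
  annual nodes over 2–20 (19) and 3–20 (18) for the proportion parameters.
* **Medians**: a saturating-exponential interpolation between a
  domain-start anchor and an age-20 anchor per sex, giving smooth,
  strictly monotone M(t) for size parameters. Anchor magnitudes emulate
  achondroplasia anthropometry — adult height near 131/124 cm (m/f),
  macrocephalic head circumference, high BMI, high relative sitting height
  declining slightly with age. They were fixed once, from the condition's
  descriptive literature, and are not calibration knobs.
* **Scale and skewness**: S varies smoothly over the domain (SD units of
  realistic magnitude for identity parameters, CV ≈ 0.10–0.15 for weight
  and BMI) with ±2% seeded jitter so curves are not exactly collinear; L
  for Box-Cox parameters drifts smoothly through negative values with
  small jitter. The ranges are capped so that |L·S| ≤ 0.22, keeping the
  inverse transform well-defined out to |z| = 4 with margin.

Every bundle passes the validator with zero violations and is byte-stable
under a fixed seed. What the fixtures do **not** emulate: sampling noise of
a fitted reference (real LMS curves wiggle), secular trends, measurement
protocol differences, or the true covariance between parameters within a
child. Green tests on synthetic bundles therefore demonstrate that the
*computation* is correct, not that any particular published chart is —
clinical use requires loading the licensed coefficients.

## Cohorts with known ground truth

`generate_cohort()` builds validation patients whose true z is known
exactly because every value is produced by the inverse transform. Design
choices: ages are stratified — odd-indexed patients sit exactly on grid
nodes (interpolation must be exact there), even-indexed ones strictly
between nodes (interpolation must actually run); true z is standard normal
truncated at |z| = 4 (beyond ±4.6 the Box-Cox inverse can leave its
support for the most skewed synthetic curves, and a cohort generator that
occasionally aborts is worse than a 1-in-10⁵ tail truncation); each
parameter additionally receives one z = +4 and one z = −4 observation to
probe the percentile boundaries. A 30-patient cohort yields roughly 250
(patient, parameter) pairs, since parameters outside a young patient's age
domain are simply absent.

## The independent oracle and the agreement check

The strongest end-to-end check scores every cohort measurement twice: with
the engine, and with `manual_zscore()` — a deliberately crude re-enactment
of manual chart reading that searches bracketing rows with an explicit
loop over a flat table, interpolates each coefficient by hand, hardcodes
which parameters are Box-Cox, and evaluates the printed formulas directly.
It shares no interpolation, dispatch or transform code with the engine, so
100% agreement at 1e-9 (the package's acceptance quantity, recomputed by
`scripts/acceptance.R`) is two independent derivations meeting, not one
code path compared with itself. The tolerance 1e-9 is far below any
clinical rounding and far above double-precision noise for z-magnitudes up
to 4.

## The simulated reliability study

`simulate_rater_study()` reproduces the *design* of an inter-rater
comparison — raters × cases × 9 parameters × 2 methods, 54 calculations
per rater in the standard 3-case configuration — with a synthetic error
model, because human rater data cannot be regenerated computationally.
Manual chart reading contributes |N(0, σ)| absolute z deviation, with
σ = 0.2 as default: a chart reader interpolating between printed centile
lines is plausibly accurate to about a fifth of an SD, which puts the
simulated pooled manual median (≈ 0.13, the half-normal median 0.2·√2·erf⁻¹(½))
in the same order as reported manual-method deviations. The automated
method reproduces its own gold standard, so its deviations are exactly 0
by construction (an optional `smart_digits` argument models read-off
rounding). This is a labelled modelling stand-in for illustrating the
summary machinery — never an estimate of real rater behaviour.
Median/IQR summaries use linear interpolation between order statistics
(`stats::quantile` type 7, the mainstream default), which the summary
outputs depend on and tests pin down.

## Problem sizes and determinism

The shipped verification runs at desk scale, chosen as the smallest sizes
that exercise every code path: 18-curve bundles, 30-patient cohorts
(~250 scored pairs) for agreement, 5–30 patients for property suites, and
up to 60 simulated raters for the half-normal convergence check. All
generators are pure functions of their seed; they save and restore the
caller's RNG state, so package calls never perturb a user's simulation
stream.

## Known limitations

* Linear coefficient interpolation differs (slightly) from spline-based
  interpolation on coarse grids; users comparing against tools that
  interpolate differently should expect discrepancies well below 0.01 z on
  6-month grids but potentially larger on annual ones.
* The identity-mode S convention (SD, not CV) is asserted per bundle, and
  the validator's CV heuristic cannot catch every mislabelled column.
* No growth-velocity or longitudinal modelling: each visit is scored
  independently.
* Synthetic bundles are structural stand-ins; no clinical conclusion
  should be drawn from z-scores against them.
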