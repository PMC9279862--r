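---
title: "Estimating fractional flow reserve from pressure-flow curves: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fractional flow reserve from pressure-flow curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffr3d)
```

## The problem

Fractional flow reserve (FFR) grades a coronary stenosis by the pressure it
costs at maximal hyperemia: FFR = P_d/P_a, with ischemia conventionally
called at FFR ≤ 0.80. A bench flow loop can measure everything about a
stenosis *except* hyperemia itself — pharmacological vasodilation has no
in-vitro counterpart. The estimation strategy implemented here solves that
with two ingredients:

1. an empirical characterization of the stenosis, the pressure-drop versus
   flow curve ΔP(Q) measured at the patient's own aortic pressure, and
2. a population model of the maximally vasodilated microvasculature, a
   linear flow versus distal-pressure relation.

Their intersection *is* the hyperemic operating point: the flow the
microvasculature would draw at the distal pressure that this very flow
leaves behind the stenosis.

## Models

### Stenosis: quadratic through the origin

The fitted family is fixed at ΔP = A·Q + B·Q² with A, B ≥ 0. The two terms
are the standard decomposition of stenotic losses — viscous (linear in Q)
and expansion/separation (quadratic) — and the zero intercept is physical:
a rigid loop at zero flow drops no pressure. We deliberately fit nothing
richer (no cubic, no intercept): seven averaged points give little room, and
an intercept would absorb sensor offsets into a nonphysical degree of
freedom.

The synthetic generator uses the same family with coefficients derived from
geometry. A is the *excess* Poiseuille loss of the stenosed segment over a
same-length healthy segment, (128·μ·L/π)·(1/d_s⁴ − 1/d₀⁴), so a 0%
stenosis contributes exactly nothing; B is a Young-type expansion loss,
(K_e·ρ/2)·(A₀/A_s − 1)²/A₀² with K_e = 1.52. Working fluid defaults are a
blood analog: μ = 4.5 cP, ρ = 1.04 g/cm³. All internal hydraulics are SI;
the user-facing units are clinical (mmHg, mL/min, mm).

### Microvasculature: the CFR-P_d line

Maximal-vasodilation flow is modelled as Q = m·(P_d − P_zf). The zero-flow
pressure P_zf defaults to 20 mmHg, a physiologically realistic value for
the residual distal pressure at which flow ceases. Published fits of this
line do not come with printed coefficients, so the slope is parameterized
through interpretable quantities instead of being hard-coded:
m = CFR·Q_rest/(P_normal − P_zf), with resting flow Q_rest = 50 mL/min (a
3 mm vessel; resting flow is deliberately *not* scaled with stenosis
severity, since resting flow is preserved until near-occlusion), a normal
coronary flow reserve CFR = 3.5 and a healthy hyperemic distal pressure
P_normal = 90 mmHg. The defaults give m = 2.5 mL/min/mmHg. CFR = 3.5 and
P_normal = 90 are modelling choices — typical textbook values for normal
microvasculature — and are configurable.

### The intersection

Substituting P_d = P_a − ΔP(Q) into the line gives
m·B·Q² + (1 + m·A)·Q − m·(P_a − P_zf) = 0. Because g(Q) =
m·(P_a − P_zf − ΔP(Q)) − Q is strictly decreasing with g(0) > 0 whenever
P_a > P_zf, the positive root is unique. It is evaluated in the
cancellation-free form

$$Q_h = \frac{2m(P_a - P_{zf})}{(1 + mA) + \sqrt{(1 + mA)^2 + 4mB \cdot m(P_a - P_{zf})}}$$

which stays accurate as m·B → 0 and reduces to the linear solution at
B = 0. A bisection solver exists only as a test oracle; the closed form is
verified against it over a thousand random configurations in the test
suite. From the root: P_d = P_a − ΔP(Q_h), FFR = P_d/P_a, and the distal
resistance R_d = (P_d − P_zf)/Q_h, which algebraically equals 1/m — a
useful internal consistency check the tests assert.

FFR is read at the intersection's P_d, not interpolated back onto measured
points.

## Measurement processing

**Averaging before fitting.** Each bench protocol records three replicate
sweeps through the same ascending flow setpoints; replicates are matched by
sweep position (the recorded flow itself is noisy, so matching by value
would be circular), averaged per setpoint, and the averaged curve is
fitted. A record whose P_d exceeds P_a by more than 1% of P_a is rejected
with a warning — small negative pressure drops are expected noise near zero
flow, larger ones indicate a sensor problem.

**Weighting.** Under multiplicative sensor noise the variance of an
averaged pressure drop is σ_P²·(P̄_a² + P̄_d²)/n_rep: known up to the common
factor σ_P² from the measured pressures alone. The fit therefore defaults
to weights w ∝ n_rep/(P̄_a² + P̄_d²). The obvious alternative — empirical
1/sd² weights from the per-setpoint replicate standard deviations — is
offered but not default: with triplicate sweeps each sd carries two degrees
of freedom, and the weight noise measurably inflates the coefficient
variance.

**Non-negativity.** If the unconstrained weighted fit turns a coefficient
negative, the active-set candidates (each coefficient clamped to zero) are
refitted and the feasible fit with the smallest weighted residual sum of
squares wins. With two parameters this enumeration is the exact solution of
the constrained problem; no quadratic-programming machinery is warranted.

**Uncertainty.** First-order propagation of independent relative sensor
errors gives a relative sd of √(σ_Pd² + σ_Pa²) on the pressure ratio
P_d/P_a and σ_Q on the flow ratio. At the default 0.5% per sensor the
pressure-ratio uncertainty is √2·0.5% ≈ 0.71% — within the ~1% bound
expected of a well-calibrated pressure-wire/flow-probe bench. The tests
cross-check the closed form against Monte-Carlo.

## The synthetic generator

The generator emulates the bench experiment: constant P_a per vessel (the
downstream needle valve that physically maintains it is abstracted away,
as is pressure-wire drift, which the bench protocol handles procedurally),
triplicate sweeps over seven flow setpoints, and independent zero-mean
Gaussian relative errors (defaults 0.5% flow, 0.5% per pressure sensor) on
every reading. The nominal sweep is 20–220 mL/min; for severe stenoses the
top of that range would drive P_d below zero, so per-vessel setpoints are
capped where ΔP reaches 80% of P_a — the software analog of a bench
operator staying within physiological flows. `simulate_measurements()`
itself refuses unphysical setpoints rather than silently clipping.

Cohorts sample percent diameter stenosis from a truncated normal with mean
53.7 and sd 17.1 on [0, 95] — the profile of an intermediate-stenosis
clinical population — and draw reference diameter (3 ± 0.4 mm on
[2, 4.5]), lesion length (20 ± 5 mm on [5, 40]) and aortic pressure
(90 ± 10 mmHg on [60, 120]) from typical clinical values. Patient-specific
microvasculature is emulated by jittering each vessel's true CFR line:
lognormal slope factor (sd 0.15) and Gaussian P_zf (sd 2 mmHg, truncated to
[5, 35]). Each vessel's ground-truth FFR is computed from its *own* line
with the same intersection solver the pipeline uses, so noise-free
round-trips must agree to numerical precision — an invariant the tests
enforce at 10⁻⁶. Under these frozen defaults a 2000-vessel cohort puts the
ischemic fraction (true FFR ≤ 0.8) in the mid-50s of percent, matching the
prevalence such clinical cohorts report.

What passing tests on this generator do *not* show: the generator is
steady-flow, rigid-walled, Newtonian, single-segment and branch-free, with
strictly Gaussian multiplicative noise and a quadratic ΔP–Q law by
construction. Agreement between pipeline and truth here validates the
estimation machinery, not the physical fidelity of any bench loop; pulsatile
flow, compliant walls, collateral flow and model misspecification of the
ΔP–Q family are all outside what these tests can certify.

## Statistical conventions

The concordance suite mirrors standard validation-study practice: Spearman
rank correlation (p by t-approximation; an exact small-sample option
delegates to `stats::cor.test`), paired t-test for the mean comparison (the
field's reports often leave the paired test unnamed; the paired t is our
declared choice), Bland–Altman bias with 1.96·sd limits (sample sd, n − 1)
and proportional bias as the Spearman correlation of differences against
pair means, and an empirical ROC over all distinct estimate thresholds
(predicted positive: estimate ≤ t) with trapezoidal AUC, DeLong 95% CI (via
pROC), a Youden-optimal threshold with ties broken toward higher
specificity and then toward the lower threshold, and Clopper–Pearson exact
intervals for sensitivity and specificity (via `stats::binom.test`). The
tests verify the AUC against exhaustive concordant-pair counting and the
exact intervals against direct binomial tail inversion.

## Numerical and degenerate-input choices

- Rank-deficient designs (fewer than three distinct setpoints) and
  single-class ROC references are errors, not silent NA.
- Constant inputs to the rank correlation are an error (the correlation is
  undefined), zero-variance differences fail the paired test explicitly.
- All simulation entry points take a seed and restore the caller's RNG
  state; identical configuration and seed give byte-identical artifacts,
  and every written report embeds the seed and an MD5 hash of its
  configuration.

## Problem sizes

The test suite runs the solver-oracle sweep at 1000 random configurations,
noise-free round-trips over a 100-vessel cohort, the noisy recovery study
at 200 seeded repetitions of a 60% stenosis, cohort shape checks at 2000
(truth only) and 28 (full pipeline) vessels, and Monte-Carlo noise checks
at 10⁴–10⁵ draws; the whole suite completes in well under a minute on one
CPU.

## Known limitations

- The quadratic coefficient B is intrinsically the harder parameter: a
  triplicate seven-point sweep at 0.5% sensor noise leaves its median
  relative error in the low single-digit percents even for an efficient
  weighted estimator, a few-fold above the linear coefficient's. FFR itself
  is far more stable (its seed-to-seed sd is an order of magnitude below a
  clinically meaningful difference) because the intersection averages over
  the fitted curve.
- The CFR-P_d line is a population-level stand-in for a patient's
  microvasculature; per-patient slopes, if available, should be passed via
  `cfr_line_from_slope()`.
- Serial lesions, side branches and collateral flow violate the
  two-resistance series model and are out of scope.
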