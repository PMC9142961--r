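---
title: "Methods: decay-chain modelling, counting reduction and efficacy analysis"
author: "alphachain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decay-chain modelling, counting reduction and efficacy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphachain)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the synthetic-data tests do and
do not demonstrate about real data.

## The decay chain and the Bateman solution

The ²²⁵Ac chain is modelled as a strictly serial list of nuclides with
per-link branching fractions: ²²⁵Ac (9.9 d) → ²²¹Fr (5 min) → ²¹⁷At
(32.3 ms) → ²¹³Bi (45.6 min) → stable ²⁰⁹Bi. The half-lives are the values
used in the study protocol this pipeline is designed around; nuclide charts
tabulate ²²¹Fr at 4.8 min, and since nothing downstream depends on the
rounding at the sub-percent level, the packaged YAML (`ac225_chain.yaml`)
keeps the protocol values and lets the user override them. The ²¹³Bi branch
split (²¹³Po/²⁰⁹Tl) is collapsed to a single effective link of branching 1:
no counting window downstream of ²¹³Bi is used anywhere in the analysis, so
the split never enters a measurable quantity.

`bateman_activities()` evaluates the closed-form Bateman solution in atom
space (atoms = activity / λ) and converts back to activities. Two numerical
choices matter:

* **²¹⁷At is collapsed by default.** Its decay constant is ~2.6 × 10⁷ times
  ²²⁵Ac's; at every timescale a counter can resolve it is in instantaneous
  equilibrium with ²²¹Fr. Removing it keeps the partial-fraction
  denominators well conditioned. The full four-member solution remains
  available (`ac225_chain(collapse_at217 = FALSE)`) and agrees with a stiff
  ODE integration to better than 10⁻⁶ relative over two weeks (the tests
  and the acceptance script both measure this at 25 time points × 4
  members).
* **Near-degenerate decay constants.** When any two λ agree within 10⁻⁹
  relative, the distinct-λ formula would divide by a vanishing difference.
  The solver then switches to the exponential of the bidiagonal rate
  matrix, which evaluates the confluent limit exactly rather than
  approximately perturbing the half-lives.

Internal units are minutes and kBq, with converters at the boundary
(`to_minutes()`, the `unit` arguments).

`equilibrium_ratio()` returns the asymptotic daughter/parent activity
ratio; for a single link it reduces to λ_d/(λ_d − λ_p), and it refuses
chains in which any intermediate decay constant does not exceed the
parent's (no transient equilibrium exists).

## Counting reduction to %IA/g

Samples and 1%-of-injected-dose standard aliquots are counted
*simultaneously*, so radioactive decay between injection and counting
cancels in the sample/standard ratio and the default reduction applies no
explicit decay correction:

%IA/g = counts / mean(standard counts) × fraction × 100 / mass.

An explicit `decay_factor` argument exists for asynchronous runs. Background
is subtracted only when a background column is supplied (whether the
original counts were background-subtracted is generally not reported in
study protocols); negative net counts floor at zero with a warning, and
%IA/g values are never clamped.

**Delayed parent quantification.** ²²⁵Ac is measured through the ²²¹Fr
window (170–270 keV) at ≥ 24 h after dissection, when every free daughter
present at dissection has decayed and the window reflects only
parent-supported activity. The equilibrium-ratio correction
λ_Fr/(λ_Fr − λ_Ac) ≈ 1.00035 converts progeny-window signal to
parent-equivalent activity and is applied by default. A subtlety worth
recording: when the standards are themselves parent aliquots counted in the
same window at equilibrium — the normal protocol — the factor cancels out
of the ratio, so applying it introduces a ≈ 0.035% bias. This is an order
of magnitude below the counting error of the 1% aliquots at realistic
activities, and the correction is toggleable
(`equilibrium_correction = FALSE`).

## Free versus supported ²¹³Bi

The continuous ²¹³Bi-window trace of a freshly dissected organ follows

Y(t) = (Y0 − plateau) · e^(−kt) + plateau · g(t),

where the excess ("free") component decays with k = ln 2 / 45.6 min and the
supported component follows the parent, g(t) = e^(−λ_Ac t). Design choices:

* **k is fixed by default.** The decay constant of ²¹³Bi is a physical
  constant; estimating it from each trace (the generic curve-fitting
  behaviour) only adds variance. Free-k mode is retained as a diagnostic
  and flags fits whose k deviates > 20% from the physical value. Which
  variant the original Prism analyses used is not stated in study reports;
  fixed-k is this package's choice.
* **The plateau drifts.** Over a 12-h trace the supported level decays by
  1 − e^(−λ_Ac·720 min) = 3.4%. With `parent_correction = TRUE` (default)
  the model absorbs this exactly; the plain constant-plateau model is
  selectable and carries a bias of that order, which the test suite bounds.
* **Weights and uncertainties.** Bin counts are Poisson; rates at bin
  midpoints are fitted by weighted least squares with weights 1/variance.
  Because the variance is known (not estimated from residuals), parameter
  covariance uses unit dispersion, which is what makes the 95% CI of the
  free component calibrate against generator truth (~92–96% empirical
  coverage over 200 simulated organs, measured by the acceptance script).
  With fixed k the model is linear in its two amplitudes and solved
  exactly; free-k profiles k over that exact solution with
  `stats::optimize`.
* **Midpoint evaluation.** Basis functions are evaluated at bin midpoints
  in both generator and fit; over 5-min bins against a 45.6-min half-life
  the midpoint-vs-integral discrepancy is below 10⁻³ and cancels between
  the two.

`decompose_bismuth()` prefers a late equilibrium record (≥ 10 × 45.6 min
after dissection; records earlier than that are refused) for the supported
level, converted to %IA/g against its own simultaneous standards, and uses
the fit only for the dimensionless ratio Y0/plateau. The fitted plateau
serves as a flagged fallback. Free components may be negative (a deficit,
as in blood) and are never clamped. The equilibrium-record threshold
defaults to the ten-half-life criterion; the common "~24 h after
dissection" protocol comfortably satisfies it.

## Tumor growth, endpoints and survival

Tumor volume is the ellipsoid V = 4/3·π·a·b·c on caliper radii. Doubling
time is obtained by ordinary least squares on ln V versus day — equivalent
to a nonlinear exponential fit on noiseless data and more stable under
multiplicative noise; animals with non-positive slope (shrinking tumors)
are excluded from doubling-time summaries rather than treated as errors,
and any animal with at least three positive-volume measurements enters the
fit regardless of why its series ended.

Humane endpoints convert trajectories into survival records by earliest
crossing: tumor volume ≥ 2 cm³; weight loss > 15% within 2 days, evaluated
on a daily grid linearly interpolated between weigh-ins (protocols do not
define the window arithmetic; a sliding 2-day comparison on the
interpolated series is this package's definition); weight loss > 20% from
baseline (first recorded weight); ulceration and clinical deterioration as
input flags, since they cannot be computed from numbers. Ties are broken
in that order. Animals with no crossing are censored at the predefined
study end (day 150 post-inoculation by default); the time origin is the
inoculation day. Kaplan–Meier curves and the log-rank test go through the
survival package; the median is reported as "not reached (> end)" when the
curve never falls to 0.5.

Group comparisons follow the conventions of such studies: independent
t-tests with Levene's test (mean-centered; Brown–Forsythe selectable)
gating pooled versus Welch in `auto` mode — the variant used is always
recorded, never silently switched; ANOVA and Kruskal–Wallis (mid-rank tie
correction) for more than two groups; two-sided α = 0.05 throughout;
pairwise survival comparisons unadjusted by default with Holm available by
flag, matching the unadjusted pairwise reporting style of the field.

## What the generators emulate — and what they do not

The synthetic cohorts reproduce the *statistical structure* the analysis
assumes: lognormal inter-animal spread of uptake around organ means
(uptake is positive and reported as mean ± SD, making the lognormal the
natural minimal model, parameterised by mean and CV); Poisson counting
with per-window efficiencies, flat background and 5-min bins over 720 min
(counter efficiency, background and bin width are not reported by
protocols; the defaults — 0.25–0.35 counts/decay, 1 cpm, 5 min — are
documented choices and everything downstream is relative, so absolute
efficiency cancels); multiplicative lognormal caliper noise of 5% CV per
radius; initial tumor volumes lognormal around a median of 82.9 mm³;
doubling times lognormal around 31.9 d (control) with the reported
inter-animal spread; treated trajectories piecewise-exponential
(shrink-then-regrow), since published growth curves show but do not
parameterise regrowth.

They deliberately do **not** model antibody pharmacokinetics, the
anatomical route by which relocated ²¹³Bi reaches the kidney, spectral
crosstalk between windows, counter dead time, or immune effects. Passing
round trips therefore demonstrates that the *reduction and inference
machinery* is unbiased and calibrated under the stated noise model — not
that the noise model exhausts real animal data.

One arithmetic caveat recorded for transparency: a control arm with median
initial volume 82.9 mm³ and median doubling time 31.9 d crosses 2 cm³ only
after day 150 under pure exponential growth, so under these published
parameters most simulated control animals are censored; survival contrasts
in the examples use faster-growing demonstration scenarios where events
are needed.

## Problem sizes and determinism

Every generator takes an integer seed and is exactly reproducible;
re-running a report with the same seed and config reproduces its CSVs byte
for byte. The validation suites use sizes chosen to make their tolerances
meaningful at interactive runtimes: 25 time points for the ODE
cross-check; 200 seeded organs (100 kidney-like at R = 5, 100 blood-like
at R = 0.2) for decomposition calibration; cohorts of n = 5 per timepoint
for biodistribution round trips; n = 10 per arm for doubling-time
recovery; 2000 replicates for the empirical size of the log-rank test and
10,000 label shuffles for its permutation cross-check.

## Known limitations

* Dosimetry (absorbed dose, RBE) is out of scope; the pipeline stops at
  activity concentrations.
* Window quantification assumes no crosstalk correction is needed beyond
  the window definitions themselves.
* The one-phase model assumes the free component is pure ²¹³Bi; a sample
  also accumulating free ²²¹Fr would bias the early bins, which the
  ten-half-life equilibrium logic does not address (²²¹Fr's 5-min
  half-life makes this a minutes-scale transient).
* The delta-method CI of the free component mildly undercovers (~92–95%
  observed vs 95% nominal) because the ratio Y0/plateau is not exactly
  normal at finite counts.
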