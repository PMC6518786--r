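---
title: "Testing for a circadian rhythm of death: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for a circadian rhythm of death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circamort)
```

This vignette is the package's own account of the statistics it
implements: what each model assumes, which tunable parameters matter, what
the synthetic generator does and does not emulate, and where the design
was genuinely open and a choice had to be made.

## The question and the data model

The unit of analysis is one death record: a time of day at minute
resolution (0–1439 minutes after midnight), a cause category (cancer,
ischemic heart disease, pneumonia, or other), age in whole years, and sex.
The scientific question is whether times of death deviate from uniformity
over the 24-hour clock — a circadian rhythm — once the day is treated as
what it is, a circle. All analyses use time of day only; calendar
structure (day of week, season) is deliberately out of scope.

Hour bins are half-open clock intervals [h:00, h+1:00): a death at
exactly 6:00 belongs to hour 6. Rejected input rows (unparseable times,
ages, labels) are counted and reported, never imputed — with registration
artifacts a live concern, silent fixes are dangerous.

## The parametric sinusoidal circadian test

Minutes map linearly to angles, θ = 2πt/1440. For n angles the mean
resultant length is

R̄ = ‖(mean cos θ, mean sin θ)‖₂ ∈ [0, 1],

and the test statistic is Z = n R̄². Under uniformity Z is asymptotically
Exp(1), giving the first-order p-value p = e^(−Z); this is the default
(`method = "simple_exponential"`). The classical higher-order series
correction,

p = e^(−Z) [1 + (2Z − Z²)/(4n) − (24Z − 132Z² + 76Z³ − 9Z⁴)/(288n²)],

is available as `method = "corrected"`; at registry scale (n in the tens
of thousands) the two agree to many digits, so the default is the simpler
mapping, whose Z → p relationship is also the one reproduced exactly in
the acceptance suite. The test is consistent against any alternative with
a nonzero first circular harmonic — a unimodal sinusoidal rhythm is the
canonical such alternative, but asymmetric registration artifacts also
project onto the first harmonic (the analysis stages demonstrate this:
cause-neutral count heaping at two non-antipodal hours leaves a small
population resultant that registry-scale n can detect).

Assumptions worth stating: observations are treated as independent draws
from one circular density; minute discretization is ignored (1440 support
points are effectively continuous for this statistic — no grouping
correction is applied); the test has no power against alternatives whose
first harmonic vanishes, e.g. a perfectly symmetric 12-hour pattern.

A cosinor-style check is provided separately (`cosinor_test()`): Poisson
log-linear regression of the 24 hourly counts on one sine/cosine pair,
with a 2-df likelihood-ratio test. "Sinusoidal test" can reasonably mean
either construction; offering both lets users verify that conclusions do
not hinge on the choice.

## The excess-mass multimode test

The nonparametric route asks a different question: does the time-of-death
density have one mode or more? For a level λ and k disjoint closed
intervals C₁…C_k, the excess mass is E_k(λ) = sup Σⱼ [F_n(Cⱼ) − λ|Cⱼ|];
the statistic is Δ = max_λ [E₂(λ) − E₁(λ)], the extra probability mass a
second mode can claim. Δ is computed exactly via the identity Δ = 2·dip(F_n),
with the dip obtained by the greatest-convex-minorant /
least-concave-majorant algorithm on the sorted sample (C++
implementation). The identity is not taken on faith: the test suite
checks the production algorithm against a brute-force optimizer that
enumerates all interval pairs with endpoints at data points and maximizes
over the induced critical grid of λ values (upper-envelope breakpoints),
at tolerance 1e−12 across hundreds of random small samples.

Calibration uses the critical-bandwidth bootstrap: the smallest Gaussian
KDE bandwidth at which the estimate is unimodal is found by bisection
(relative tolerance 1e−3, mode counting on a 2048-point grid), and
bootstrap samples are drawn from that just-unimodal KDE with the usual
variance rescaling. The p-value is (1 + #{Δ_b ≥ Δ_obs})/(n_boot + 1); the
default n_boot = 500 resolves p down to about 0.002, and the result is
bit-reproducible given (seed, n_boot).

Two behaviours deserve emphasis:

* **Ties.** Minute-resolution times carry heavy ties, which the dip
  machinery (built for continuous data) reads as point modes. By default,
  integer ties are broken with seeded uniform jitter within ±0.5 minute —
  one recording unit — before computing Δ. The policy is recorded in the
  result's `method_notes` and can be disabled.
* **Near-flat densities.** A uniform density is the boundary case of
  unimodality: every point is a mode. The critical-bandwidth calibration
  is anti-conservative there — the just-unimodal KDE is smoother than the
  flat truth, its resamples produce smaller dips, and tiny observed Δ
  values (order 0.01 on clock times) can come back highly significant.
  The package's registry-scale synthetic runs show exactly this pattern:
  excess mass ≈ 0.004–0.009 with bootstrap p at its resolution floor.
  A rejection of "one unique mode" on near-uniform data should therefore
  be read as "not exactly unimodal", not as evidence of a meaningful
  second peak. The unimodal-calibration acceptance check runs at a
  genuinely peaked null (Gaussian), where the bootstrap holds its size.

Clock time is circular, but the statistic is computed on the line
[0, 1440) by default — the natural behaviour of an off-the-shelf
multimode test applied to clock values, and the reading most likely to
match common practice. A circular variant (`circular = TRUE`) minimizes Δ
over cut points of the circle; it is never larger than the linear
statistic. Exact minimization tries every gap between adjacent sorted
values, which is quadratic in n; above `max_cuts` (default 512) distinct
values the variant switches to quantile-spaced cuts, a negligible
approximation at the sample sizes where it triggers. Bootstrap replicates
are always evaluated on the line, which can only make the circular
variant conservative.

## Prevalence-ratio regression

The descriptive question "at which hours is a cause over-represented?" is
answered with the modified-Poisson prevalence-ratio estimator: for index
cause c, the binary outcome Y = 1{cause = c} over all deaths follows the
log-link working model

log E[Y] = β₀ + Σₕ βₕ·1{hour = h} + β_sex·1{male} + β_age·age,

with h ranging over 23 dummies against the reference hour 0:00–0:59, age
entering linearly (per 1 year), and a heteroskedasticity-robust HC0
sandwich covariance replacing the misspecified Poisson variance. Then
PR = exp(β) with 95% Wald intervals exp(β ± 1.96·SE). At registry n no
small-sample correction is warranted. No multiplicity adjustment is
applied across the 23 simultaneous hour contrasts — the table mirrors the
conventional presentation — and the report notes as much.

The comparison group is implicit: deaths of all other causes in the same
hour. An hour with records but no outcome events cannot identify its
log-PR; such terms are dropped (merged into the reference) with a logged
warning rather than silently exploding. An alternative aggregate reading
— a Poisson count model of per-hour cause totals with the all-cause hour
total as offset — is available behind `form = "aggregate"`; it reproduces
the crude hour ratios but cannot adjust for individual age and sex, and
being saturated (one count per cell) it uses the classical Poisson
covariance, since a sandwich estimator degenerates when every hat value
is 1. The individual-level form is the default because it is the standard
prevalence-ratio estimator for adjusted binary outcomes.

## Restricted cubic splines

The deaths-by-hour figure is smoothed with a three-knot restricted
(natural) cubic spline: basis [1, x, s(x)] with

s(x) = [(x−t₁)³₊ − (x−t₂)³₊ (t₃−t₁)/(t₃−t₂) + (x−t₃)³₊ (t₂−t₁)/(t₃−t₂)] / (t₃−t₁)²,

which is linear beyond the boundary knots and has exactly three free
parameters. Knots default to the 10th/50th/90th percentiles of the
record-level hour variable, the most widely used rule when knot locations
are not prespecified; they can be overridden. The fit is ordinary least
squares on the 24 hourly counts at bin midpoints — the curve is
descriptive, not a count likelihood — with a Poisson log-link option when
non-negativity matters.

Two structural limitations are inherent and intentional. The curve is fit
on the line, so hour 23 does not join hour 0 (no periodic stitching);
and because the tails are linear, the spline cannot form a local peak
near either end of the day — a rhythm with a near-midnight acrophase will
surface as a monotone trend, not a bump. The peak-tracking test therefore
exercises a mid-day acrophase.

## The synthetic generator: what it emulates, and what it does not

Times of day are drawn from the mixture
π_u·Uniform[0, 1440) + (1 − π_u)·g(θ − μ), where g is cardioid,
f(θ) = (1/2π)(1 + 2ρ cos(θ − μ)), by default — its density is exactly a
sinusoid, the alternative the parametric test targets, and ρ ≤ 0.5 keeps
it non-negative — or von Mises for sharper peaks (the concentration is
specified as the mean resultant length and converted to κ internally).
Continuous draws are floored to integer minutes; ties are expected, as in
real data. Optional heaping multiplies the time density within listed
hours by given factors via rejection reweighting, emulating registration
artifacts at administratively salient times.

Demographics are calibrated to a large hospital registry: cause shares
16.5% cancer / 6.1% ischemic heart disease / 26.0% pneumonia / 51.4%
other; per-cause male shares 0.567 / 0.520 / 0.560 (0.55 for other);
per-cause ages from truncated normals centred at the registry medians
70 / 82 / 85 (75 for other) with SDs 15 / 13 / 12 (18) and truncation at
the registry extremes. The time default is π_u = 1 — uniform, the
arrhythmic regime a null-dominated registry suggests — with ρ = 0.3 and
μ = 360 (6 am) as the rhythmic component whenever a rhythm is switched
on. One global seed drives deterministically derived per-stage sub-seeds,
so identical configs give bit-identical record streams.

What the generator does **not** emulate: reporting-delay dynamics (times
shifted minutes-to-hours after the terminal event), resuscitation-driven
survival prolongation, cause-misclassification, calendar structure, or
any dependence of the *time* distribution on cause, age, or sex — every
record draws its time from the same mixture. Consequently, passing tests
show that the pipeline's statistics behave correctly under known circular
structure and clean demographics; they say nothing about robustness to
delayed or misattributed registration in real registries. A separate
generator (`sample_pr_records()`) produces records whose cause indicator
follows a designed log-linear hour/sex structure, as ground truth for the
prevalence-ratio machinery — there the time–cause dependence is the point.

## Numerical choices and degenerate inputs

* Dip computation keeps all distances in count units (multiples of 1/n)
  and divides by 2n once at exit; comparisons driving the control flow
  are exact. A constant sample returns Δ = 0 (a single-step CDF is
  already unimodal); n < 3 is an error.
* Critical-bandwidth bisection: initial bracket from the sample SD,
  doubling upward / halving downward as needed.
* Bootstrap p-values use the (1 + exceedances)/(n_boot + 1) convention;
  p = 1/(n_boot + 1) is printed as an inequality. n_boot below the
  requested resolution warns, n_boot = 0 errors.
* Empty aggregation selections give zero counts with n = 0, not errors;
  empty circular samples error (no angles to summarise).
* Ages outside a configurable plausible range (default [0, 120]) warn
  but are kept — registry maxima reach 117.
* Degenerate spline designs (non-increasing or collapsed knots,
  rank-deficient basis) are hard errors with instructions to supply
  knots explicitly.

## Problem sizes in the test and acceptance suites

The suites run entirely from synthetic data at desk scale, chosen as the
smallest sizes at which the asymptotic behaviours under test are stable:
2,000 replicates of n = 500 for the circadian test's type-I error, 500
for its power against ρ = 0.2; 300 unimodal and 150 bimodal samples of
n = 300 with 200 bootstrap replicates for excess-mass calibration; 200
replicates of n = 50,000 for prevalence-ratio recovery and coverage; and
a 353,827-record cohort in the analysis stages, matching the registry
scale the pipeline is designed for.

## Known limitations

* The resultant-length test targets first-harmonic departures only, and
  cannot distinguish a biological rhythm from an asymmetric registration
  artifact with the same harmonic content.
* The excess-mass calibration is anti-conservative at near-flat
  densities (see above); its rejections on clock-time data warrant a
  look at the actual Δ magnitude.
* Prevalence ratios compare causes against all other causes of death in
  the same hour; with an external population denominator the estimand
  would differ.
* The spline overlay is non-periodic and tail-linear by construction.
* Race is carried through ingestion and simulation but is not a model
  covariate anywhere in the pipeline.
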