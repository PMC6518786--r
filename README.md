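# circamort

Do in-hospital deaths cluster at particular times of day? Claims of a
circadian rhythm of death — morning peaks for cardiac arrest, nocturnal
peaks in palliative wards — are common but often rest on small samples and
informal multiple comparisons. `circamort` packages the statistical
pipeline needed to ask the question properly from registry-scale death
records: circular encoding of clock times, a parametric sinusoidal test of
24-hour periodicity, a nonparametric multimodality test, prevalence-ratio
regression of cause-specific death by hour of day, and restricted cubic
spline summaries for the familiar deaths-by-hour figure. It is aimed at
epidemiologists and biostatisticians working with individual death records
(time of death to the minute, cause, age, sex).

Because registry extracts are rarely shareable, the package ships a
synthetic death-record generator with tunable circadian structure, so every
stage of the pipeline — and every test in the suite — runs without external
data.

## Methods at a glance

* **Circular encoding.** A time of death *t* (minutes since midnight) maps
  to the angle θ = 2π·t/1440. A sample of angles is summarised by its mean
  resultant length R̄ ∈ [0, 1] and mean direction (the acrophase estimate).
* **Parametric sinusoidal circadian test.** Uniformity on the circle is
  tested against a unimodal sinusoidal alternative with the
  resultant-length (Rayleigh-type) statistic Z = n·R̄², with p = e^(−Z)
  (first order; a higher-order corrected p-value is available for small n).
* **Excess-mass multimode test.** H₀: one unique mode. The excess-mass
  statistic Δ = max_λ [E₂(λ) − E₁(λ)] is computed exactly as twice the
  Hartigan dip of the empirical CDF (greatest-convex-minorant /
  least-concave-majorant algorithm, implemented in C++), and calibrated by
  a smoothed bootstrap from the kernel density estimate at the critical
  bandwidth — the smallest bandwidth whose Gaussian KDE is unimodal.
* **Prevalence-ratio regression.** Modified Poisson estimation: a log-link
  working model for the binary cause indicator with 23 hour dummies
  (reference 0:00–0:59), sex, and linear age, with HC0 sandwich
  (robust) variance. PR = exp(β), 95% Wald intervals.
* **Restricted cubic splines.** Hourly death counts are smoothed with a
  three-knot natural cubic spline (linear beyond the boundary knots),
  knots at the 10th/50th/90th percentiles of the hour variable.
* **Synthetic records.** Times come from a mixture of a uniform component
  and a cardioid (or von Mises) rhythmic component with concentration ρ and
  acrophase μ; cause shares, per-cause age and sex distributions follow a
  large hospital registry; optional count heaping at chosen clock hours
  mimics registration artifacts such as shift changes.

## Worked example

Generate 50,000 deaths carrying a weak 6 am rhythm (cardioid, ρ = 0.05)
and run the pipeline:

```r
library(circamort)

cfg <- sim_config(n = 50000, rho = 0.05, pi_uniform = 0, mu = 360, seed = 2024)
rec <- sample_records(cfg)

circadian_test(rec)
#> Parametric sinusoidal circadian test (resultant length)
#>   n = 50000, Rbar = 0.0479
#>   Z = 114.650, P = 1.615e-50  (simple_exponential)

excess_mass_test(rec$time_of_day, n_boot = 500, seed = 11)
#> Nonparametric multimode test (H0: one unique mode)
#>   n = 50000, excess mass = 0.005776
#>   P < 0.002 (no bootstrap exceedances in 500 replicates)

tab <- fit_pr(rec, "cancer")
tab[match(c("hour_6", "sex_male", "age"), tab$term), ]
#>   term     coefficient robust_se    pr conf_low conf_high
#> 1 hour_6       -0.0263  0.0658   0.974    0.856     1.11
#> 2 sex_male      0.0748  0.0200   1.08     1.04      1.12
#> 3 age          -0.0248  0.000508 0.976    0.975     0.977

fit_spline(aggregate_counts(rec, "hour"))
#> Restricted cubic spline fit (3 knots at 2.50, 11.50, 21.50; identity link)
#>   RSS = 2.843e+05; fitted range 1899.5 - 2255.3
```

Reading the output: the injected rhythm is weak (R̄ ≈ 0.05) but n is
large, so Z = n·R̄² is overwhelming — the sinusoidal test detects it.
The excess-mass statistic is tiny (0.006): the density is close to flat,
yet the bootstrap rejects "one unique mode", a known behaviour of
critical-bandwidth calibration at near-flat densities. The cause-specific
PRs are flat across hours (the rhythm affects all causes alike, so it
cancels from prevalence ratios), while the sex PR of 1.08 simply reflects
the registry's per-cause sex mix. `make_report()` bundles the same results
with a two-panel deaths-by-hour/minute figure.

The `analysis/` directory holds the same pipeline as numbered stages
(`01_simulate.R` … `05_report.R`) run on a full 353,827-record synthetic
cohort, writing tables and figures under `results/`.

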