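---
title: "Methods: stochastic-model-based SI variability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic-model-based SI variability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sivar)
```

## The problem

Model-based insulin sensitivity (SI) identified hourly at the ICU bedside is
highly dynamic. Sudden large *rises* in SI are the dangerous direction: an
insulin dose chosen for the current SI can then drive glucose into
hypoglycemia before the next measurement. `sivar` quantifies how variable a
patient's SI is relative to what a whole-cohort reference model predicts,
and how that variability evolves with day of stay and differs between
diagnosis groups (operative/non-operative x cardiac/gastric/other, six
groups derived from APACHE III codes).

## The stochastic transition model

All hourly transitions $(SI_n, SI_{n+1})$ of the cohort — every patient,
every day pooled — are turned into a conditional distribution of next-hour
SI by bivariate kernel density estimation. `sivar` places one Gaussian
kernel per transition on the *log* scale, $(u_i, v_i) = (\log SI_n, \log
SI_{n+1})$, because SI is positive and right-skewed; Gaussian kernels on the
log scale respect that support exactly. Conditioning on a current value $x$
gives a mixture:

$$F(y \mid x) = \sum_i w_i(x)\,\Phi\!\left(\frac{\log y - v_i}{h_{v,i}}\right),
\qquad w_i(x) \propto \phi\!\left(\frac{\log x - u_i}{h_{u,i}}\right),$$

with weights normalised to 1. The default bandwidths follow Silverman's rule
per dimension over all centres; an optional k-nearest-neighbour rule scales
them per centre by local density. When a dimension has degenerate spread,
the bandwidth falls back to `max(1e-3, 1e-2 * |centre|)` so the CDF stays
proper. Quantiles invert the CDF by an expanding bracket plus bisection on
the log scale to 1e-10 in probability; under Gaussian kernels the CDF is
strictly increasing, so the root is unique.

## Percentiles and the two penalty metrics

Each observed hour is scored as the percentile of the actual $SI_{n+1}$ on
its predicted distribution, $p = F(SI_{n+1} \mid SI_n)$ — the probability
integral transform (PIT). A perfectly calibrated model yields percentiles
uniform on $[0, 1]$; that uniformity is the reference everywhere below. The
first hour of a stay has no predecessor and yields no percentile; records
are timestamped at the observed hour.

Two per-patient aggregates are computed per day block:

* **quadratic penalty** $= \operatorname{mean}\{(p - 0.5)^2\} \in [0, 0.25]$
  — overall variability. Uniform percentiles give $1/12 \approx 0.0833$;
  a patient pinned to the predicted median gives 0.
* **one-sided threshold penalty** $=$ fraction of $p > 0.9$ (strict) —
  large upward swings, the hypoglycemia-risk direction. Uniform percentiles
  give 0.10; more than 10% flags above-reference risk. Exceedance is
  defined on the percentile rather than on raw SI against a precomputed
  quantile; under a proper CDF the two are equivalent and the former is
  numerically cleaner. Ties at the threshold have probability zero under a
  continuous model, so the strict inequality is a fixed but immaterial
  choice.

Percentiles are kept as fractions in $[0,1]$ throughout; thresholds are
configuration-exposed.

## Day-of-stay segmentation

Patients discharge at different times, so naive averaging would weight
patients unequally. Scores are therefore computed over *complete* 24-h
blocks only: day 1 = [0, 1440) min, day 2 = [1440, 2880), day 3 =
[2880, 4320), and day 4+ = everything from 4320 min on (day 4+ is
inherently open-ended and keeps all remaining records). A day-1/2/3 block is
retained only when the stay covers its end; stays under 24 h are excluded
entirely.

## Mixed-effects inference

The per-hour percentile records (not per-day averages) are the observation
unit: time enters at minute precision and only varies within patients below
day resolution. Observations beyond 8000 min (~5.5 days) are dropped — the
variability-versus-time relation is biphasic over long stays, and the
restriction confines the models to the early, approximately linear regime.

For the quadratic response, the per-hour squared deviation $(p-0.5)^2$ is
rescaled by 4 onto $(0,1)$, clamped to $[10^{-6}, 1-10^{-6}]$, and
logit-transformed to map the skewed bounded score to an approximately
normal scale. The linear mixed model is fitted by REML (`nlme`):

$$y_{ij} = \textstyle\sum_{k=1}^{6} \beta_k d_k(i) + \beta_T t_{ij}
  + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},$$

cell-means coding (six group intercepts, no global intercept, one common
time slope) with correlated per-patient random intercept and slope. For the
binary exceedance indicator the same fixed and random structure is fitted
as a logistic-binomial GLMM by Laplace approximation (`lme4`), without the
residual term. Time is fitted in days for optimizer stability and reported
per minute and per day ($\times 1440$).

Model-selection companions, all by ML likelihood ratios: necessity of the
random intercept (1 df) and random slope (2 df — variance plus covariance;
both nulls sit on the variance boundary, so the naive chi-square p-values
are conservative, which is recorded in the output rather than corrected);
continuous-time AR(1) within-patient residual correlation (`corCAR1`, 1 df,
with a tagged Ljung-Box fallback if the joint fit fails numerically); and
the 5-df Time x Diagnosis interaction, whose non-rejection licenses the
common-slope model. Post-hoc, all 15 pairwise group contrasts are tested
with single-step (Tukey HSD-type) family-wise adjustment from the joint
normal distribution of the contrasts.

## The synthetic cohort generator

No clinical SI dataset accompanies the method, so the generator is a
first-class module that encodes the structure the analysis assumes and is
itself under test. Each patient follows a log-scale random walk with drift:

$$\log SI(t+60) = \log SI(t) + s_i + \eta_t, \qquad
  \eta_t \sim N\!\left(0,\; \sigma_1^2\, \delta^{2t/1440}\, m_g^2\right),$$

with lognormal baseline, normal random slope $s_i$, innovation SD largest
at admission ($\sigma_1$) decaying by factor $\delta$ per day, and a
group-specific multiplier $m_g$. This is the simplest process that is
positive, right-skewed, and reproduces the qualitative facts the analysis
targets: day-1 variability peak, decay over roughly four days, gastric
least and cardiac most variable.

Defaults (chosen once as clinically plausible scales, not estimates —
the generator's parameters are free knobs): median stay 96 h (lognormal,
log-SD 0.6, truncated at 24 h so every patient qualifies for daily
statistics; a flag re-admits shorter stays for exclusion-path testing),
baseline median SI 3 (nominal 1e-4 L/mU/min units, log-SD 0.5),
$\sigma_1 = 0.25$, $\delta = 0.7$, slope SD 0.002/h, multipliers
NOpC 1.25, OpC 1.2, NOpG 0.8, OpG 0.9, NOpO 1.0, OpO 1.0. A master seed
spawns per-patient substreams, so cohorts are reproducible and stable under
reordering.

What the generator does *not* emulate: glucose/insulin/nutrition dynamics,
measurement error in SI identification, informative discharge or death,
drug effects, or any real joint distribution of diagnosis with severity.
Passing tests therefore demonstrate that the pipeline recovers structure
*of this kind* — signs, orderings, calibration — not clinical magnitudes.

## Numerical and design choices

* **Self-calibration nulls.** A cohort sampled from the fitted model and
  scored by the same model has exactly uniform percentiles, so decile
  coverage (10% per bin), mean one-sided penalty (10%) and mean quadratic
  penalty (1/12) are exact references up to binomial/Monte-Carlo error.
  The test suite checks these at 10,000 transitions.
* **Quartile convention** is linear interpolation between order statistics
  (R type 7). **LOWESS** uses span 2/3 with 3 robustness iterations.
* **Oracle checks.** The conditional CDF is validated against adaptive
  quadrature of the conditional density (1e-6), quantiles against brute
  grid inversion, and sampling against the CDF by Kolmogorov-Smirnov.
* **Problem sizes.** The bundled experiments run at desk scale: training
  cohorts of ~50-120 patients (5,000-12,000 transitions), 50 replicates
  for the sign-recovery experiments with 8 patients per group and ~60-h
  stays. These sizes were chosen so the full suite runs in minutes while
  leaving the Monte-Carlo error well inside the asserted margins.
* **Convergence is flagged, never patched.** Non-converging mixed-model
  fits return a flagged result object; nothing falls back silently.

## Known limitations

* The per-hour observation unit for the mixed models is an interpretation
  (per-day averages are also supported via the penalty tables); with
  minute-precision time and the paper-style restriction both are defensible.
* The exact logit pre-scaling of the quadratic response (here: x4 onto
  (0,1), clamp 1e-6) is a package choice; alternatives shift the
  coefficients monotonically without affecting signs or contrasts.
* Variance-boundary LR tests report naive chi-square p-values with a
  conservativeness note; no 50:50 mixture correction is applied.
* On cohorts whose variability genuinely decays, the pooled whole-cohort
  model is miscalibrated *within* each day (over-dispersed early, under-
  dispersed late) — that is the effect being measured, so per-group or
  per-day reference models are deliberately out of scope.
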