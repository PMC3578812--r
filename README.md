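# sivar — insulin-sensitivity variability in intensive care

`sivar` quantifies the hour-to-hour variability of model-based insulin
sensitivity (SI) in ICU patients and how it evolves with day of stay and
diagnosis. Large sudden *rises* in SI are the clinically dangerous
direction: insulin dosed on the current SI can then drive blood glucose
into hypoglycemia before the next measurement. The package is aimed at
glycemic-control researchers who have (or simulate) hourly SI trajectories
and want a calibrated, inferential description of their variability.

## The method

1. **Stochastic model.** All hourly transitions `(SI_n, SI_{n+1})` of the
   cohort — every patient and day pooled — are fitted by bivariate kernel
   density estimation on the log scale. Conditioning on the current value
   gives, for each hour, a predicted distribution of next-hour SI:

   `F(y | x) = Σ_i w_i(x) Φ((log y − v_i)/h_v,i)`, `w_i(x) ∝ φ((log x − u_i)/h_u,i)`.

2. **Percentiles.** Each observed hour is scored as the percentile (the
   probability integral transform) of the actual `SI_{n+1}` on its
   predicted distribution. A perfectly calibrated model gives percentiles
   uniform on [0, 1].

3. **Penalties, per patient per day block** (day 1/2/3 = complete 24-h
   intervals, day 4+ = the rest; stays < 24 h excluded):
   - *quadratic* `mean((p − 0.5)²)` ∈ [0, 0.25] — overall variability
     (uniform reference: 1/12 ≈ 0.083);
   - *one-sided* fraction of `p > 0.9` — hypoglycemia-inducing upward
     swings (uniform reference: 0.10).

4. **Inference.** Cell-means linear mixed model (REML, `nlme`) on the
   logit-transformed quadratic penalty and a logistic-binomial GLMM
   (Laplace, `lme4`) on the exceedance indicator, both with six diagnosis
   intercepts, a common time slope, and per-patient random intercept +
   slope; LR tests for the random structure, AR(1) and interaction; Tukey
   HSD contrasts for all 15 group pairs (`multcomp`).

A seeded synthetic-cohort generator with the structure the analysis assumes
(lognormal SI, day-1 variability peak decaying over ~4 days, gastric least /
cardiac most variable) makes every stage testable without clinical data.

## Worked example

```r
library(sivar)

cohort <- generate_cohort(cohort_config(n_patients_per_group = 10, seed = 2026))
cohort
#> si_cohort: 60 patients, 7082 hourly observations

model <- fit_stochastic_model(extract_transitions(cohort))
model
#> si_stochastic_model: 7022 transitions, log transform, silverman bandwidths
#> (h_u ~ 0.1792, h_v ~ 0.1802)

scores <- per_patient_day_scores(cohort, model)
aggregate(cbind(quadratic, one_sided) ~ day, scores, mean)
#>        day  quadratic    one_sided
#> 1     day1 0.06202176 0.0500000000
#> 2     day2 0.03856978 0.0154320988
#> 3     day3 0.02173591 0.0009469697
#> 4 day4plus 0.01035760 0.0000000000
```

Day 1 is the most variable and both penalties decay with stay — the pooled
model is over-dispersed relative to late, settled days. The mixed model
turns this into estimates:

```r
seg <- segmented_percentiles(cohort, model)
fit <- fit_lme_quadratic(build_observations(seg, "quadratic"))
fit
#> si_mixed_model (nlme, REML, quadratic response)
#>    NOpC     OpC    NOpG     OpG    NOpO     OpO
#> -1.3709 -1.4018 -2.3854 -1.9758 -1.7676 -1.8575
#> Time: -0.000441236 per minute (-0.6354 per day)

tk <- tukey_hsd(fit)
head(tk[order(tk$p_adjusted), ], 3)
#>     comparison   estimate        se         z        p_raw   p_adjusted
#> 2  NOpG - NOpC -1.0145090 0.1251330 -8.107445 5.169537e-16 1.887379e-15
#> 6   NOpG - OpC -0.9836316 0.1203977 -8.169857 3.087543e-16 9.547918e-15
#> 11 NOpO - NOpG  0.6178485 0.1183511  5.220472 1.784679e-07 3.461814e-06
```

The group coefficients are each group's (logit-scale) variability at
admission: gastric non-operative lowest, cardiac highest, matching the
generator's configured ordering. The negative time coefficient is the
common per-day decline; `time_coefficient_per_day(fit)` converts the
per-minute estimate. The Tukey table singles out exactly the contrasts the
simulation built in (NOpG below both cardiac groups).

`run_pipeline(pipeline_config(...))` chains all stages and writes every
table (cohort, model, percentiles, penalties, decile coverage histograms
with chi-square uniformity tests, LOWESS trends, distribution summaries,
model coefficients, Tukey contrasts) as CSV plus a checksummed manifest.
`inst/scripts/run_pipeline.R` is a thin command-line wrapper.

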