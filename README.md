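# splitmr

Split-sample Mendelian randomization (MR) pipelines for estimating causal
effects of education, body mass index, lifetime smoking and alcohol
consumption on **multimorbidity** — the presence of two or more chronic
conditions — together with mediation and additive-interaction analyses.

## Who this is for

Epidemiologists and biostatisticians who want a tested, reusable
implementation of the full split-sample MR workflow on individual-level
cohort data: exposure/outcome derivation from questionnaire-like fields,
per-split GWAS and instrument construction, two-stage least squares,
meta-analysis of the split estimates, multivariable-MR mediation and
product-instrument interactions — plus a synthetic biobank generator with
*exactly computed* ground-truth effects, so every stage is verifiable by
parameter recovery rather than faith.

## The statistical core

For exposure X, outcome Y (a linear-probability risk difference scale) and
a standardized polygenic score Z discovered in the *other* half of the
cohort (GWAS p ≤ 5×10⁻⁸, greedy LD clumping at r² < 0.001 within 10,000 kb,
proxies at r² ≥ 0.8):

* **2SLS**: β̂ = (X'P_Z X)⁻¹ X'P_Z y with instrumental-variable sandwich
  standard errors; covariates (age, sex, centre, genetic PCs) enter both
  stages. Per-split estimates β̂₁, β̂₂ are pooled by fixed-effects
  inverse-variance meta-analysis, with heterogeneity
  I² = max(0, 100·(Q − df)/Q).
* **Mediation** (difference method): PM = 100·(total − direct)/total,
  where the direct effect comes from multivariable MR instrumenting
  education and the mediator(s) jointly; percentile bootstrap CIs over
  individuals (200 repeats); inconsistent mediation (|direct| > |total| or
  sign flip) suppresses PM. A parametric g-formula estimator is the
  binary-outcome sensitivity analysis.
* **Additive interaction**: exposures {A, B, A·B} instrumented by
  {PRS_A, PRS_B, PRS_A·PRS_B, PRS_A²}; the interaction beta has null
  value 0 on the risk-difference scale.
* **Sensitivity estimators** over the clumped variants: IVW, MR-Egger
  (intercept = directional pleiotropy test), unweighted median, simple
  mode.
* **Exposures**: years of education inferred from highest qualification;
  BMI = weight/height²; the lifetime smoking index
  (1 − 0.5^(dur/τ))·0.5^(ces/τ)·ln(cigs+1) with τ = 18.9 years; weekly
  alcohol units from per-beverage counts (never-drinkers 0 and retained,
  former drinkers excluded, >200 units/week excluded). Effects are
  reported per SD education, per 5 kg/m², per SD smoking index, per 5
  units/week.

## Worked example

Simulate a small biobank-like cohort, build cross-split instruments, and
estimate the education → multimorbidity effect and its mediation by BMI:

```r
library(splitmr)

arch <- lapply(default_architecture(), function(a) { a$n_causal_snps <- 8; a })
cfg  <- sim_config(n_individuals = 6000, n_snps = 400,
                   architecture = arch, seed = 7)
panel <- simulate_genotypes(cfg)
sim   <- simulate_cohort(panel, cfg)
sim$truth
#> <true_parameters>
#>   true risk differences (mm2, per scaled unit):
#>     education  -0.0899
#>     bmi        +0.0919
#>     smoking    +0.0679
#>     alcohol    +0.0129
#>   proportion mediated (%):
#>     bmi          20.7
#>     smoking      17.1
#>     alcohol      -3.6
#>     bmi+smoking  37.9

data <- add_scaled_exposures(derive_exposures(sim$cohort))
inst <- build_instruments(data, panel,
                          covariates = c("age", "sex", paste0("pc", 1:10)),
                          seed = 7)
mr <- split_mr_estimate(inst$data, "education", "mm2",
                        covariates = c("age", "sex", "centre",
                                       paste0("pc", 1:10)))
mr$pooled
#> # A tibble: 1 × 11
#>      beta     se ci_low ci_high           p scale     q    df    i2     k
#> 1 -0.0919 0.0180 -0.127 -0.0567 0.000000319 <NA>  0.149     1     0     2
```

One SD more education (≈5.1 years) lowers multimorbidity risk by an
estimated 9.2 percentage points (pooled over the two half-samples,
I² = 0) — recovering the generator's true total effect of −0.0899 well
inside one standard error. Mediation through BMI:

```r
med <- mediation_analysis(
  build_analysis_set(inst$data, c("education", "bmi"), "mm2"),
  "education_std", "bmi_per5", "mm2",
  covariates = c("age", "sex", "centre"), framework = "mr",
  instruments = c(education_std = "prs_education", bmi_per5 = "prs_bmi"),
  n_boot = 200, seed = 7)
med
#> <mediation_result> MR, mediator(s): bmi_per5
#>   total    -0.0921 (se 0.0179)
#>   direct   -0.0790 (se 0.0177)
#>   indirect -0.0131 (95% CI -0.0205, -0.0070)
#>   proportion mediated 14.3% (95% CI 7.5, 23.3)
```

At this small n the PM estimate (14.3%, CI 7.5–23.3) brackets the true
20.7%. `run_study()` orchestrates the whole thing — simulation,
derivation, instruments, MVR-vs-MR effect tables, sensitivity estimators,
mediation (MVR, MR and g-formula) and interactions — and
`generate_report()` writes the five result tables;
`plot_effects()`, `plot_ratios()` and `autoplot()` draw the standard
figures, and `tidy()`/`glance()` extract rectangular summaries from fitted
objects.

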