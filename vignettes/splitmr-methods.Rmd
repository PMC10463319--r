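---
title: "Methods: split-sample Mendelian randomization for multimorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-sample Mendelian randomization for multimorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Multimorbidity — living with two or more chronic conditions — is strongly
patterned by education, adiposity, smoking and alcohol use, but ordinary
regression of multimorbidity on these exposures is confounded by everything
that jointly shapes behaviour and health. `splitmr` implements a causal
analysis of this question with Mendelian randomization (MR): genetic
variants associated with an exposure are used as instrumental variables, so
that the exposure-outcome estimate inherits the (near-)random allocation of
genotypes rather than the social patterning of the exposure itself.

The design is a *split-sample* MR. The cohort is divided into two random
halves; within each half a GWAS of each exposure is run, genome-wide
significant variants (p <= 5e-8) are LD-clumped (r^2 < 0.001 within a
10,000 kb window, proxies at r^2 >= 0.8), and the clumped variants define a
polygenic risk score (PRS) weighted by the discovery coefficients. Each
half's score is then applied *only in the other half* — avoiding
winner's-curse/sample-overlap bias — as the instrument in a two-stage least
squares (2SLS) model with robust standard errors, adjusted for age, sex,
assessment centre and genetic principal components. The two half-sample
estimates are pooled by fixed-effects inverse-variance meta-analysis with
an I^2 heterogeneity statistic. All outcomes are modelled with linear
probability models, so every effect is a risk difference (RD) per scaled
exposure unit: one SD of education years, 5 kg/m^2 of BMI, one SD of the
lifetime smoking index, 5 alcohol units/week.

Three further procedures are layered on this machinery:

* **Mediation** of the education effect through BMI, smoking and alcohol by
  the difference method: total effect (education alone) minus direct effect
  (education with the mediator(s) included — as covariates in multivariable
  regression, or as jointly instrumented exposures in multivariable MR).
  The proportion mediated is PM = 100 (total − direct) / total, with
  percentile bootstrap intervals over individuals (200 repeats by default,
  resampled within split for MR). When the direct effect exceeds the total
  in magnitude or differs in sign, mediation is *inconsistent* and PM is
  suppressed rather than reported. A parametric g-formula estimator
  (logistic outcome model + Gaussian mediator model, Monte-Carlo
  standardization) provides a sensitivity analysis that respects the binary
  outcome.
* **Additive interactions** between exposure pairs: a product term in the
  robust linear regression, and in MR a multivariable 2SLS with exposures
  {A, B, A x B} instrumented by {PRS_A, PRS_B, PRS_A x PRS_B,
  PRS_A x PRS_A}. The squared score instruments the product's curvature and
  attaches to the declared upstream exposure; education is always upstream
  of the behavioural exposures, otherwise the first-listed exposure is
  treated as A (reorder the pair to override).
* **Ratio-based sensitivity estimators** over the clumped variants — IVW,
  MR-Egger (its intercept tests directional pleiotropy), the unweighted
  median and the simple mode — computed per split on
  discovery-exposure/application-outcome associations and meta-analysed.
  Computing them per split and pooling is a convention of this package; the
  split-specific variant sets are small, so pooled-set estimates would
  differ slightly.

## The synthetic cohort and its ground truth

No individual-level biobank data can ship with a package, so the unit of
verification is a synthetic biobank generator whose *every* structural
parameter is known, and whose implied causal contrasts are computed exactly
rather than estimated.

The generator (`sim_config()`, `simulate_genotypes()`, `simulate_cohort()`)
draws:

* **Genotypes**: biallelic SNPs in exchangeable-correlation LD blocks
  (default 10 SNPs per block, haplotype correlation 0.8, 50 kb spacing,
  MAF uniform on [0.05, 0.5]), two thresholded latent-Gaussian haplotypes
  per individual. Blocks give clumping something real to remove; block
  independence keeps the ground truth tractable.
* **Education** from a standard-normal liability (polygenic component +
  confounder + noise) discretized at fixed UK-like quantiles into seven
  qualification categories, mapped to years (20/19/15/13/10/10/7). The
  realized SD of education years is about 5.1.
* **BMI, smoking, alcohol** each as own-polygenic-score + education effect
  + confounder + noise. Smoking is generated as raw behaviour fields
  (status, cigarettes/day, duration, cessation) by *inverting* the lifetime
  smoking index formula, so the derived index — not some latent proxy —
  carries the intended structure; alcohol is decomposed into per-beverage
  weekly counts whose unit-weighted sum reproduces the latent weekly units
  up to rounding. A configurable 4% of drinkers are flagged former drinkers
  (with elevated condition liability) to exercise the exclusion rule, and
  never-drinkers are retained at 0 units.
* **35 chronic conditions** from probit (liability-threshold) models: each
  condition's liability is a condition-specific multiple of a shared
  exposure score, plus confounder, age, sex and former-drinker terms;
  thresholds are solved numerically so each condition hits its prevalence
  target (defaults: hearing loss 37%, depression/anxiety 35%, painful
  condition 29%, a geometric tail; multimorbidity 2+ lands near 55%, the
  prevalence of a middle-aged cohort).

**Ground truth is a computation, not a simulation.** For any counterfactual
shift of the scaled exposures, the per-condition probabilities are probit
evaluations, and the probability of 2+/3+/4+ conditions follows from the
Poisson-binomial elementary symmetric polynomials; averaging the shifted
minus unshifted probabilities over the generated sample gives the true risk
difference exactly (to floating point) for that sample. The generator
*calibrates* the liability loadings by root-finding so these implied true
RDs equal the configured targets — defaults −0.090 per SD education
(total), +0.092 per 5 kg/m^2, +0.068 per SD smoking index, +0.013 per 5
units/week, magnitudes chosen to mirror plausible biobank-scale effects.
Education's target is its *total* effect: its counterfactual propagates to
the mediators through the structural coefficients (exactly for BMI, which
is linear; via the average-derivative linearization
`edu_smoking x P(smoker)` and `edu_alcohol x P(drinker)` for the
zero-censored behaviours). Mediation truth (total, direct with mediators
held fixed, indirect = total − direct, PM) and additive-interaction truth
(the double difference of the outcome probability under joint and single
shifts) are computed the same way and written to `truth_report()`. An
optional `target_pm` calibrates the mediator loading so the true PM hits a
requested percentage; `interactions` targets calibrate the
liability-scale product coefficients to a requested interaction RD.

A single standard-normal confounder U loads on every exposure and every
liability, so multivariable regression is biased away from the truth in a
known direction while valid instruments are not — the package's central
demonstration. Analyses involving alcohol switch to multimorbidity
definitions that exclude the alcohol-problems condition and drop excluded
drinkers, and the ground truth mirrors both choices.

### What the generator does not emulate

Realistic human LD maps, imputation, population stratification (PCs are
noise independent of genotype), relatedness, sex chromosomes, genetic QC
failures, and the questionnaire idiosyncrasies of any real biobank. The
GWAS engine is plain covariate-adjusted least squares per SNP; a mixed
model adds nothing without relatedness, but this is a fidelity gap with
respect to real pipelines. Passing recovery tests therefore shows the
estimators are correct under the stated model, not that any real-data
estimate is unbiased.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `p_threshold` | 5e-8 | GWAS selection threshold |
| `r2_threshold`, `window_kb` | 0.001, 10,000 | clumping; proxies use r^2 >= 0.8 |
| `tau` | 18.9 | smoking-index half-life, years |
| scalings | SD, 5, SD, 5 | education, BMI (kg/m^2), smoking, alcohol (units/wk) |
| `n_boot` | 200 | mediation bootstrap repeats; percentile CIs are noisy at 200 — raise it for smooth intervals |
| median/mode bootstrap | 1000 | parametric draws for SE of the robust estimators |
| `phi` | 1 | mode-estimator bandwidth factor (modified Silverman rule) |
| weak-instrument warning | F < 10 | warning only, never fatal |
| CI multiplier | 1.96 | large-sample normal intervals throughout |

## Numerical choices

* Clumping is greedy in ascending p, ties broken by ascending variant id,
  making results invariant to input row order; the analysis panel itself is
  the LD reference.
* Proxy ties break by higher r^2, then smaller distance, then id.
* GWAS p-values come from the exact t distribution, so small test panels
  are exact; SNPs with constant adjusted dosage are skipped with a warning.
* 2SLS standard errors are the IV sandwich computed from `y − X beta`
  (never second-stage OLS residuals) with an HC1 factor; OLS uses HC1;
  logistic models use the plain ML sandwich.
* IVW and MR-Egger use multiplicative random-effects scaling floored at
  the fixed-effect SE. The mode estimator's bandwidth guard falls back to
  the SD when the MAD degenerates to zero.
* I^2 is truncated at zero; a single-split pool is flagged
  (`single_split`) rather than dropped so report schemas stay rectangular.
* Every random stage draws from a named substream of one master seed
  (`substream_seed()`), so the full pipeline is byte-identical on re-run.
* Degenerate inputs error early and specifically: empty instrument sets,
  zero-variance scores, rank-deficient designs (with the collinear columns
  named), under-identification, missing CMMS weights, unmapped
  qualifications.

## Design choices where the design was open

* The qualification-years mapping, the CMMS weight table and the
  beverage-units conversion are *inputs*, shipped as editable tables under
  `inst/extdata/` (the CMMS table is synthetic and labelled as such);
  nothing downstream hard-codes them.
* The inconsistent-mediation rule is |direct| > |total| *or* opposite
  signs; the second clause guards PM > 100% artifacts and is flagged when
  it triggers.
* MR mediation pools total and direct effects across splits first and
  forms indirect/PM from the pooled values; per-split estimates are kept
  alongside. The bootstrap resamples individuals within split.
* The g-computation Monte-Carlo uses 10,000 draws from a fixed substream
  with common random numbers across counterfactual scenarios.
* The package's functions (with `run_study()` as the single `all`
  orchestrator), the test suite and `scripts/acceptance.R` are the
  interface; no separate command-line binary is shipped.

## Problem sizes

The packaged verification runs use a cohort of 20,000 individuals with
2,000 SNPs (30 causal per exposure, 15% of exposure variance explained, so
split-half instruments reach F in the hundreds), 500 null replicates for
2SLS type-I error and 200 for the MR interaction test, and 200-repeat
bootstraps. These sizes make every recovery check decisive at three
standard errors while a full study completes in about two minutes; unit
tests use cohorts of 3,000-8,000. Estimates at these sizes carry
Monte-Carlo error of roughly 0.01 on the risk-difference scale — the test
tolerances are stated in units of each estimate's own standard error, not
as fixed constants.

## Known limitations

* The linear-probability estimand and the probit-generated truth agree
  only approximately when effects are large or prevalences extreme; at the
  default moderate effects the discrepancy is well inside one standard
  error at n = 20,000.
* The education counterfactual linearizes the mediator response of the
  censored behaviours (smoking, alcohol); with strong education effects on
  them the linearization would drift from the exact counterfactual.
* MR-Egger is weakly identified when variant-exposure effects are
  homogeneous, which equal-variance causal architectures encourage; its
  intercept test retains validity but its slope is imprecise.
* The 200-repeat default bootstrap gives PM interval endpoints that are
  themselves noisy (the repeat count is kept configurable for exactly this
  reason).
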