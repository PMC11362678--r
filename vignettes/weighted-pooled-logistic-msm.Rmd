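---
title: "Marginal structural survival analysis for two-wave exposures"
author: "poolmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural survival analysis for two-wave exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmsm)
```

## The estimation problem

`poolmsm` estimates the causal effect of a binary exposure measured at two
waves (five years apart in the motivating design: a living-arrangement
questionnaire answered twice) on discrete-time mortality over the `K = 14`
years that follow the second wave. The exposure can change between waves,
and the time-varying covariates measured at wave 2 are both *affected by*
the wave-1 exposure and *confounders of* the wave-2 exposure. This
exposure–confounder feedback is exactly the situation in which regression
adjustment fails and g-methods are required: conditioning on the wave-2
covariates blocks part of the wave-1 effect, while ignoring them leaves the
wave-2 exposure confounded.

The package therefore fits a marginal structural model by inverse
probability weighting. The estimand is the counterfactual cumulative
incidence
\[
F_{a_1 a_2}(k) \;=\; 1 - \prod_{j \le k}\bigl(1 - h_{a_1 a_2}(j)\bigr),
\qquad (a_1, a_2) \in \{0,1\}^2,
\]
the risk by year \(k\) that would have been observed had everyone followed
the joint exposure regime \((a_1, a_2)\). The four regimes are labelled
`with-with`, `with-alone`, `alone-with`, `alone-alone` (1 = exposed, i.e.
living alone). Contrasts are reported as risk differences (in percentage
points) and risk ratios against the doubly-unexposed `with-with` regime at
the midpoint and the end of follow-up, not as hazard ratios: a single
hazard ratio averages over time and suffers built-in selection, whereas
the risk curves remain causally interpretable at every horizon.

## The estimation pipeline

`msm_pooled()` runs the sequence end to end; every stage is also an
exported function.

**Discrete-time hazards by pooled logistic regression.** The cohort is
expanded into person-years: subject \(i\) contributes \(T_i\) yearly rows,
with the event indicator set only in the terminal row of subjects who died
of the target cause (`expand_person_years()`). Follow-up years are indexed
\(k = 1, \dots, 14\): fourteen years of follow-up are fourteen one-year
intervals, with \(k\) entering the linear predictor as a continuous
covariate. A weighted logistic regression of the yearly event indicator on
the regime indicators and time is then the discrete-time hazard model
(`fit_pooled_logistic()`). Because yearly hazards are small, this is
numerically close to — but never approximated by — a proportional-hazards
fit; survival always uses the exact product formula.

**Stabilized exposure weights.** Two denominator models (wave 1: exposure
on baseline covariates and region; wave 2: exposure on the wave-1
exposure, baseline and time-varying covariates and region) and two
numerator models (wave 1: intercept only; wave 2: wave-1 exposure only)
give per-subject stabilized weights
\(sw_{A1} \cdot sw_{A2}\) (`fit_exposure_models()`,
`compute_exposure_weights()`). Region enters every weight model as
indicator variables (fixed effects) rather than a random effect, because a
small number of areas does not support reliable variance-component
estimation.

**Stabilized censoring weights.** Loss to follow-up is addressed by
cumulative stabilized censoring weights: pooled logistic models of the
per-year remaining-uncensored indicator, denominator conditional on time
(\(k + k^2\) by default), exposures, covariates and region, numerator on
time and exposures only. The weight at year \(k\) is the running product
of the per-year ratios (`fit_censoring_models()`,
`compute_censoring_weights()`). The numerator may condition on the
exposure history because the structural model itself does. Deaths from
non-target causes are *not* treated as loss to follow-up by default: the
censoring models address dropout, and competing deaths are handled by the
cause-specific convention below.

**Truncation and combination.** Each weight family is truncated at its
empirical 99th percentile (`truncate_weights()`): the exposure weights as
the product \(sw_{A1} sw_{A2}\), the censoring weights per person-year on
the cumulative value, upper tail only. The percentile uses the
linear-interpolation (type 7) convention, fixed so that thresholds are
reproducible; the same convention is reused for the bootstrap percentile
intervals. The final per-person-year weight is the product of the two
truncated components (`combine_weights()`). Untruncated stabilized
weights should average close to 1; `weight_diagnostics()` reports the
means, extremes and truncation counts on every fit, and the test suite
requires the means to sit within 0.05 of 1 on correctly specified
simulations.

**Cause-specific convention.** Deaths from non-target causes end follow-up
with no event (they censor the target cause at the death year). The
estimand is therefore the *net* risk — the risk that would be seen if the
competing cause were removed — and the simulator's truth oracle computes
the same quantity by default, so estimator and oracle target the same
number. A flag on the oracle retains competing events for users who want
the alternative convention.

**Counterfactual curves, contrasts, E-values.** Hazards predicted under
each regime are turned into survival and cumulative incidence by the
exact product (`build_regime_curves()`), contrasted at the chosen horizons
(`compute_contrasts()`), and screened for sensitivity to unmeasured
confounding with E-values (`compute_evalue()`):
\(E = RR + \sqrt{RR(RR-1)}\) for \(RR \ge 1\), with ratios below one
inverted first and the CI E-value computed on the limit closer to the
null (1 if the interval crosses 1).

**Percentile bootstrap.** Confidence intervals come from resampling
*subjects* (person-year rows are not exchangeable) with replacement
(`bootstrap_pipeline()`, default `B = 500`). Exposure and censoring
models, truncation thresholds and the hazard model are re-estimated inside
every replicate, so the weights' estimation uncertainty is propagated.
Pointwise 2.5th/97.5th percentiles of the replicate draws form the
intervals; replicates whose reference risk is zero are excluded from the
risk-ratio vector with the count reported, and a replicate that fails to
converge is recorded and skipped (more than 5% failures aborts the run).
The replicate loop has two interchangeable engines: a plain-R reference
implementation and a compiled single-precision path used by default —
bootstrap draws carry \(O(n^{-1/2})\) sampling noise, so single-precision
coefficient accuracy (~1e-6 relative) is irrelevant to the intervals,
and the test suite checks the two engines agree.

**Missing covariates.** Covariates are completed once, before weight
estimation, by iterative random-forest imputation (`rf_impute()`): missing
cells are initialised with the column mean/mode, then each incomplete
variable in turn (in order of increasing missingness) is regressed on all
other predictors with a 100-tree forest (`mtry = ceiling(sqrt(p))`) and
its missing cells re-predicted, until the set-level change statistic —
normalised squared change for continuous variables, proportion of changed
categories for categorical ones — first increases for every set present,
at which point the previous sweep is returned. Exposures and follow-up
variables are never imputed; subjects missing them are excluded at read
time (`read_cohort()`), mirroring the design in which exposure missingness
may be caused by intervening events. Bootstrap replicates resample the
completed table rather than re-imputing, a pragmatic choice that keeps
the replicate cost linear; re-imputation per replicate would add
imputation uncertainty to the intervals and is noted as a limitation.

## The synthetic cohort generator and its truth oracle

Because the motivating cohort is access-restricted, the package ships a
generator (`generate_cohort()`) whose causal structure matches the
analysis assumptions: baseline covariates → wave-1 exposure →
time-varying covariates (affected by the wave-1 exposure) → wave-2
exposure → yearly survival with loss to follow-up and a competing cause.
Yearly deaths are Bernoulli draws on the expit scale, so the pooled
logistic hazard model is exactly correctly specified under this process —
deliberate, since parameter-recovery tests need a well-defined truth.
Within a year the event draw precedes an end-of-year censoring draw, so a
subject lost in year \(k\) contributes a fully observed event-free year
\(k\).

Defaults emulate a middle-aged questionnaire cohort: age ~ Normal(52, 8),
binary covariates with prevalences 0.03–0.55, eleven regions, roughly
8–13% exposed per wave with strong persistence (wave-2 log-odds +3 for
wave-1 exposed), 2–3%/year loss to follow-up, a 0.8%/year competing
hazard, and ~16% missingness on a subset of covariates. A latent
health-behaviour factor correlates the diet variables with each other and
with activity/smoking, and BMI tracks age — without such correlations a
covariate imputer would have nothing to learn. The target-cause event
rate is set near an all-cause scale (reference-regime 14-year risk
~0.15–0.18) rather than the rare suicide scale, so that recovery tests
have adequate statistical power; the causal structure, not the marginal
rates, is what the tests exercise. What the generator does *not* emulate:
real marginal distributions of any specific cohort, calendar-time trends
in event rates, or exposure changes within the five-year interval.

`true_counterfactual_risks()` is the oracle: it forces both exposures to
a regime (the time-varying covariates still respond to the forced wave-1
exposure), disables loss to follow-up and — by default — the competing
cause, and reports the empirical counterfactual cumulative incidence with
its Monte-Carlo standard error.

## Numerical choices

All logistic fits use iteratively reweighted least squares with the
normal equations formed by BLAS-level operations, warm-started inside the
bootstrap; coefficients match `stats::glm()` to ~1e-12 (tested).
Possible separation (a diverging coefficient) is an error, except in
deliberately saturated categorical-time fits where zero-event years push
the corresponding hazard to 0. Denominator probabilities below a
positivity floor (1e-6) are a hard error, never silently clipped.
Sandwich (cluster-robust by subject) standard errors accompany the hazard
model as diagnostics; all reported intervals are bootstrap percentiles.
Survival uses exact products throughout — no exponential shortcut.

## Verification strategy and problem sizes

The test suite validates the pipeline against independent routes rather
than against itself:

- the Kaplan–Meier estimator (`survival::survfit`) must agree with the
  unweighted saturated-time pooled logistic curve to 1e-6 — they are
  algebraically the same estimator — and with the default smooth time
  specification to 0.02;
- `build_regime_curves()` must agree with a brute-force term-by-term
  hazard-product loop to 1e-12 on 100 random coefficient vectors;
- on a 50,000-subject cohort with confounding, exposure–confounder
  feedback and informative censoring, the pipeline's
  \(\hat F_{a_1a_2}(14)\) must sit within three standard errors of the
  oracle truth for all four regimes (combined delta-method and
  Monte-Carlo SE; the oracle uses 200,000 draws per regime), while the
  crude per-cell estimate of the persistently exposed regime is biased by
  the designed confounded amount;
- under a null-effect process with strong confounding, the weighted
  risk ratios at 14 years must stay within [0.85, 1.15] at n = 50,000;
- percentile-bootstrap calibration is measured over 200 simulated
  datasets of n = 5,000 with B = 200 replicates each, using a
  reduced-covariate configuration (age and smoking confounding, smoking
  feedback, informative censoring, four regions) chosen to keep roughly
  forty thousand pipeline refits tractable; the 95% interval for the
  persistent-exposure risk difference at 14 years must cover the oracle
  truth in 90–99% of datasets.

Passing these shows the machinery is correct *under the generator's
assumptions* — correctly specified logistic exposure, censoring and
hazard models. It does not certify performance on real data, where all
three models are approximations, measurement error exists, and exposure
can change between waves.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 20000, seed = 1)
cohort <- inject_missingness(generate_cohort(cfg), cfg)
fit <- msm_pooled(cohort, target_cause = "suicide")
summary(fit)
boot <- bootstrap_pipeline(fit, B = 500, seed = 2)
plot(fit, boot = boot)
ct <- fit$contrasts
compute_evalue(ct$rr[ct$regime == "alone-alone" & ct$horizon == 14],
               boot$contrast_ci$rr_lower[6], boot$contrast_ci$rr_upper[6])
```

Configuration-driven runs (YAML or list), including age- and
gender-stratified re-runs with the parsimonious model (no regime-by-time
product terms, as small stratum-specific event counts cannot support
them), go through `run_analysis()`; every stage logs its row counts,
event counts and seeds, and a provenance record sufficient to reproduce
the run exactly is written alongside the result tables.

## Known limitations

- Single imputation: imputation uncertainty is not propagated (no
  multiple imputation, no per-replicate re-imputation by default).
- The bootstrap resamples the completed table; with heavy missingness the
  intervals will be slightly anticonservative.
- Cause-specific (net-risk) handling of competing deaths, not an
  Aalen–Johansen sub-distribution analysis; the two answer different
  questions and the package deliberately implements the former.
- Weight models are parametric logistic fits; no machine-learning weight
  estimation or doubly-robust correction.
- The year index treats follow-up as 14 whole-year intervals; events and
  censorings within a year are not ordered beyond the stated convention.
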