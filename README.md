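# poolmsm

Causal survival analysis of a **two-wave binary exposure** on
**discrete-time mortality**, for epidemiologists analysing cohort data in
which the exposure (the motivating case: living alone, reported on two
questionnaires five years apart) can change between waves and the wave-2
covariates are both affected by the earlier exposure and confounders of the
later one. Ordinary covariate adjustment is biased under such
exposure–confounder feedback; `poolmsm` implements the g-method
alternative: an **inverse-probability-weighted pooled logistic marginal
structural model**.

## The model

For yearly intervals k = 1, …, K (K = 14) the discrete-time hazard under a
joint exposure regime (a₁, a₂) ∈ {0,1}² is modelled as

    logit h(k; a₁, a₂) = β₀ + f(k) + θ₀₁·1(a₁=0, a₂=1) + θ₁₀·1(a₁=1, a₂=0)
                         + θ₁₁·1(a₁=1, a₂=1) + (regime × k products)

fitted by weighted maximum likelihood on the person-year expansion, with
per-person-year weights

    w(k) = trunc₉₉[ sw_A1 · sw_A2 ] × trunc₉₉[ sw_C(k) ],

where sw_A1, sw_A2 are stabilized inverse-probability-of-exposure weights
(separate logistic models per wave; region as fixed effects) and sw_C(k)
is the cumulative stabilized censoring weight for loss to follow-up, each
truncated at its empirical 99th percentile. Counterfactual cumulative
incidence uses the exact product formula

    F_{a₁a₂}(k) = 1 − Π_{j≤k} (1 − h(j; a₁, a₂)),

with risk differences and risk ratios against the doubly-unexposed regime
at the midpoint and end of follow-up, percentile-bootstrap confidence
intervals (subjects resampled, all weight models re-estimated per
replicate), E-values for unmeasured confounding, and missForest-style
random-forest imputation for missing covariates. Deaths from non-target
causes censor the target cause (net-risk, cause-specific convention).

Because the motivating cohort is access-restricted, the package includes a
synthetic cohort generator with the same causal structure (confounding,
exposure-affected time-varying covariates, informative censoring, a
competing cause, covariate missingness) and a counterfactual-truth oracle;
the test suite validates the whole pipeline against that oracle. See the
vignette `vignettes/weighted-pooled-logistic-msm.Rmd` for the methods
account.

## Worked example

```r
library(poolmsm)

cfg    <- sim_config(n_subjects = 20000, seed = 1)      # study-like defaults
cohort <- inject_missingness(generate_cohort(cfg), cfg) # ~16% missing cells
fit    <- msm_pooled(cohort, target_cause = "suicide")  # impute + weight + fit
fit
```

```
Weighted pooled logistic MSM — target cause: suicide
20000 subjects, 204555 person-years, 3199 events, 5575 lost to follow-up
Counterfactual cumulative incidence at 14 years:
      regime cuminc
   with-with 0.1799
  with-alone 0.3025
  alone-with 0.2426
 alone-alone 0.4321
```

The four rows are the counterfactual 14-year risks had everyone followed
each joint exposure pattern: e.g. 0.43 is the estimated risk had everyone
been exposed at both waves (this simulated effect is far larger than any
real suicide risk; the generator trades realism of the marginal rates for
statistical power in validation). Bootstrap intervals and the E-value
screen:

```r
bt <- bootstrap_pipeline(fit, B = 200, seed = 2)
ct <- fit$contrasts
m  <- match(paste(ct$regime, ct$horizon),
            paste(bt$contrast_ci$regime, bt$contrast_ci$horizon))
ct$rr_lower <- bt$contrast_ci$rr_lower[m]
ct$rr_upper <- bt$contrast_ci$rr_upper[m]
ct[ct$horizon == 14, ]
```

```
       regime horizon cuminc cuminc_ref rd_pp   rr rr_lower rr_upper
4  with-alone      14  0.302       0.18 12.26 1.68     1.54     1.85
5  alone-with      14  0.243       0.18  6.27 1.35     1.14     1.57
6 alone-alone      14  0.432       0.18 25.22 2.40     2.19     2.62
```

`rd_pp` is the risk difference in percentage points against the
`with-with` reference; persistent exposure raises the 14-year risk by 25
points (RR 2.40, 95% CI 2.19–2.62) in this simulation. How strong would
an unmeasured confounder have to be, on the risk-ratio scale with both
exposure and outcome, to explain that away?

```r
row <- ct[ct$regime == "alone-alone" & ct$horizon == 14, ]
compute_evalue(row$rr, row$rr_lower, row$rr_upper)
#> E-value: 4.24 (point, RR = 2.40), 3.81 (CI limit)
```

`plot(fit, boot = bt)` draws the four cumulative-incidence curves with
pointwise percentile bands; `run_analysis()` drives the same pipeline
from a YAML/list configuration, including age- and gender-stratified
re-runs with the parsimonious model specification.

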