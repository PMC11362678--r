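# Shared fixtures, built in code at test time.

# Minimal subject-level table for expansion/KM tests.
make_cohort <- function(T, event, cause, A1 = 0, A2 = 0) {
  n <- length(T)
  data.frame(id = seq_len(n), A1 = rep_len(A1, n), A2 = rep_len(A2, n),
             T = T, event = event, cause_code = cause,
             stringsAsFactors = FALSE)
}

# A null-effect hazard coefficient vector for the full covariate roster:
# strong confounding retained, every exposure effect zero.
null_haz_full <- c("(Intercept)" = -7.4, k = 0.03, A1 = 0, A2 = 0,
                   "A1:A2" = 0, age = 0.045, male = 0.4, smoking = 0.5,
                   cvd_hist = 0.6, veg = -0.15, smoking2 = 0.3,
                   veg2 = -0.10)

# Small cohort reused across hazard/curve/bootstrap tests.
fixture_cohort <- function(n = 2000, seed = 42) {
  generate_cohort(sim_config(n_subjects = n, roster = "reduced",
                             n_regions = 4, seed = seed))
}

regime_labels <- c("00" = "with-with", "01" = "with-alone",
                   "10" = "alone-with", "11" = "alone-alone")

curve_at <- function(fit, regime, k, col = "cuminc") {
  fit$curves[[col]][fit$curves$regime == regime & fit$curves$k == k]
}
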