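test_that("person-year expansion follows the cause-specific convention", {
  co <- make_cohort(T = c(3, 14, 5), event = c(1, 0, 1),
                    cause = c("X70", "", "C34.9"))
  py <- expand_person_years(co, K = 14, target_cause = "suicide")
  expect_equal(nrow(py), 3 + 14 + 5)
  expect_equal(py$event[py$id == 1], c(0, 0, 1))   # suicide death at T = 3
  expect_equal(py$event[py$id == 2], rep(0, 14))   # administratively ended
  expect_equal(py$event[py$id == 3], rep(0, 5))    # competing death censors
  expect_equal(py$k[py$id == 1], 1:3)
  # competing deaths are not loss to follow-up
  expect_true(all(py$uncensored == 1))
  # the same subject is the event under the all-cause target
  py2 <- expand_person_years(co, K = 14, target_cause = "all_cause")
  expect_equal(sum(py2$event), 2)
  # lost to follow-up: terminal row flagged
  co3 <- make_cohort(T = 4, event = 0, cause = "")
  py3 <- expand_person_years(co3, K = 14)
  expect_equal(py3$uncensored, c(1, 1, 1, 0))
  expect_error(expand_person_years(make_cohort(T = 15, event = 0, cause = ""),
                                   K = 14), "1..14")
  expect_error(expand_person_years(make_cohort(T = 0, event = 0, cause = ""),
                                   K = 14), "1..14")
})

test_that("the intercept-only hazard fit is the event rate", {
  co <- fixture_cohort(n = 1500)
  py <- expand_person_years(co, 14, "suicide")
  m <- fit_pooled_logistic(py, weights = rep(1, nrow(py)),
                           time_form = "none", regime_terms = FALSE)
  expect_equal(plogis(unname(m$coefficients[1])),
               sum(py$event) / nrow(py), tolerance = 1e-10)
})

test_that("correctly specified fits recover the generating coefficients", {
  ch <- c("(Intercept)" = -6, k = 0.05, A1 = 0.3, A2 = 0.4, "A1:A2" = 0.9)
  cfg <- sim_config(n_subjects = 100000, roster = "reduced", seed = 33,
                    coef_haz = ch, coef_cens = c("(Intercept)" = -50),
                    region_sd = c(A1 = 0.2, A2 = 0.2, haz = 0, cens = 0),
                    competing_hazard = 0)
  co <- generate_cohort(cfg)
  py <- expand_person_years(co, 14, "suicide")
  m <- fit_pooled_logistic(py, weights = rep(1, nrow(py)),
                           time_form = "linear", regime_time = FALSE)
  # regime-indicator parametrization: r01 = A2 effect, r10 = A1 effect,
  # r11 = A1 + A2 + interaction
  truth <- c("(Intercept)" = -6, k = 0.05, r01 = 0.4, r10 = 0.3, r11 = 1.6)
  for (nm in names(truth)) {
    expect_lt(abs(m$coefficients[[nm]] - truth[[nm]]),
              3 * m$se_robust[[nm]])
  }
})

test_that("rescaling all weights leaves the point estimates unchanged", {
  co <- fixture_cohort(n = 1500)
  py <- expand_person_years(co, 14, "suicide")
  w <- runif(nrow(py), 0.5, 1.5)
  m1 <- fit_pooled_logistic(py, weights = w)
  m2 <- fit_pooled_logistic(py, weights = 2 * w)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
})

test_that("hazard prediction is the expit of the linear predictor", {
  co <- fixture_cohort(n = 1500)
  py <- expand_person_years(co, 14, "suicide")
  m <- fit_pooled_logistic(py)
  m0 <- m
  m0$coefficients[] <- 0
  expect_equal(predict_hazard(m0, c(0, 0), 1:14), rep(0.5, 14))
  m0$coefficients[["(Intercept)"]] <- -2.1972
  m0$coefficients[setdiff(names(m0$coefficients), "(Intercept)")] <- 0
  expect_equal(predict_hazard(m0, c(1, 1), 5), 0.1, tolerance = 1e-4)
  # monotone in a positive regime coefficient
  m1 <- m0
  m1$coefficients[["r11"]] <- 0.7
  expect_gt(predict_hazard(m1, c(1, 1), 3), predict_hazard(m1, c(0, 0), 3))
  expect_error(predict_hazard(m, c(0, 0), 15), "extrapolation")
  expect_error(predict_hazard(m, c(0, 0), 0), "extrapolation")
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  # no events: survival is one everywhere
  co0 <- make_cohort(T = rep(5, 10), event = 0, cause = "")
  km0 <- km_estimate(co0, K = 14)
  expect_true(all(km0$surv == 1))
  # no censoring: KM is the empirical cumulative survival
  co1 <- make_cohort(T = c(1, 2, 2, 3, 14, 14), event = c(1, 1, 1, 1, 0, 0),
                     cause = rep(c("X60", ""), c(4, 2)))
  km1 <- km_estimate(co1, K = 14)
  expect_equal(km1$surv[km1$k == 2], 1 - 3 / 6)
  expect_equal(km1$surv[km1$k == 3], 1 - 4 / 6)
  # censored mix, hand product-limit: times 1+, 2, 2, 3+, 4 give
  # S(2) = (4-2)/4 = 0.5 and S(4) = 0.5 * (1-1)/1 = 0
  co2 <- make_cohort(T = c(1, 2, 2, 3, 4), event = c(0, 1, 1, 0, 1),
                     cause = c("", "X61", "X61", "", "X61"))
  km2 <- km_estimate(co2, K = 4)
  expect_equal(km2$surv[km2$k == 2], 0.5)
  expect_equal(km2$surv[km2$k == 4], 0)
})

test_that("saturated-time pooled logistic reproduces the KM curve", {
  co <- fixture_cohort(n = 3000, seed = 19)
  py <- expand_person_years(co, 14, "suicide")
  m_cat <- fit_pooled_logistic(py, weights = rep(1, nrow(py)),
                               time_form = "categorical",
                               regime_terms = FALSE)
  S_cat <- cumprod(1 - predict_hazard(m_cat, c(0, 0), 1:14))
  km <- km_estimate(co, "none", "suicide", K = 14)
  expect_lt(max(abs(S_cat - km$surv)), 1e-6)
})

test_that("event accounting matches the cohort death counts", {
  co <- fixture_cohort(n = 2000, seed = 23)
  lab <- classify_cause(co$cause_code)
  for (tc in c("suicide", "non_suicide", "all_cause")) {
    py <- expand_person_years(co, 14, tc)
    want <- switch(tc, suicide = sum(lab == "suicide"),
                   non_suicide = sum(lab == "non_suicide"),
                   all_cause = sum(co$event))
    expect_equal(sum(py$event), want)
  }
})
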