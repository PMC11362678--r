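test_that("curves follow the exact hazard product", {
  co <- fixture_cohort(n = 1500)
  py <- expand_person_years(co, 14, "suicide")
  m <- fit_pooled_logistic(py)
  # zero hazard: F identically 0
  m0 <- m
  m0$coefficients[] <- 0
  m0$coefficients[["(Intercept)"]] <- -50
  cv0 <- build_regime_curves(m0)
  expect_true(all(cv0$cuminc == 0) && all(cv0$surv == 1))
  # constant hazard 0.1 over K = 3: F(3) = 1 - 0.9^3 = 0.271
  mh <- m
  mh$coefficients[] <- 0
  mh$coefficients[["(Intercept)"]] <- qlogis(0.1)
  cv <- build_regime_curves(mh, K = 3)
  expect_equal(curve_at(list(curves = cv), "with-with", 3), 0.271,
               tolerance = 1e-10)
})

test_that("curves equal a brute-force hazard-product loop on random fits", {
  co <- fixture_cohort(n = 1500)
  py <- expand_person_years(co, 14, "suicide")
  m <- fit_pooled_logistic(py)
  set.seed(99)
  for (i in 1:100) {
    m$coefficients[] <- rnorm(length(m$coefficients), 0, 0.5)
    cv <- build_regime_curves(m)
    for (key in names(regime_labels)) {
      a <- as.integer(strsplit(key, "")[[1]])
      Fk <- numeric(14)
      S <- 1
      for (k in 1:14) {  # independent slow loop, term by term
        lp <- m$coefficients[["(Intercept)"]] +
          m$coefficients[["k"]] * k + m$coefficients[["k2"]] * k^2 +
          m$coefficients[["r01"]] * (a[1] == 0 && a[2] == 1) +
          m$coefficients[["r10"]] * (a[1] == 1 && a[2] == 0) +
          m$coefficients[["r11"]] * (a[1] == 1 && a[2] == 1) +
          m$coefficients[["r01:k"]] * (a[1] == 0 && a[2] == 1) * k +
          m$coefficients[["r10:k"]] * (a[1] == 1 && a[2] == 0) * k +
          m$coefficients[["r11:k"]] * (a[1] == 1 && a[2] == 1) * k
        S <- S * (1 - 1 / (1 + exp(-lp)))
        Fk[k] <- 1 - S
      }
      got <- cv$cuminc[cv$regime == regime_labels[[key]]]
      expect_lt(max(abs(got - Fk)), 1e-12)
    }
  }
})

test_that("contrasts report RD in percentage points and RR", {
  m <- structure(list(coefficients = c("(Intercept)" = -4, k = 0, k2 = 0,
                                       r01 = 0, r10 = 0, r11 = 0,
                                       "r01:k" = 0, "r10:k" = 0, "r11:k" = 0),
                      K = 14L, time_form = "quadratic", regime_terms = TRUE,
                      regime_time = TRUE), class = "pooled_logistic")
  cv <- build_regime_curves(m)
  ct <- compute_contrasts(cv, horizons = c(7, 14))
  expect_true(all(ct$rd_pp == 0))
  expect_true(all(ct$rr == 1))
  # arithmetic: F_ref = 0.01, F_regime = 0.04 at 14 years
  cv2 <- cv
  cv2$cuminc[cv2$regime == "with-with" & cv2$k == 14] <- 0.01
  cv2$cuminc[cv2$regime == "alone-alone" & cv2$k == 14] <- 0.04
  ct2 <- compute_contrasts(cv2, horizons = 14)
  row <- ct2[ct2$regime == "alone-alone", ]
  expect_equal(row$rd_pp, 3.0)
  expect_equal(row$rr, 4.0)
  # zero reference risk: RR undefined
  cv3 <- cv
  cv3$cuminc[cv3$regime == "with-with"] <- 0
  expect_warning(ct3 <- compute_contrasts(cv3, horizons = 14), "undefined")
  expect_true(all(is.na(ct3$rr)))
  expect_error(compute_contrasts(cv, horizons = 20), "within")
})

test_that("E-values reproduce closed-form and published values", {
  ev <- compute_evalue(4.00, 1.83, 7.41)
  expect_equal(round(ev$evalue_point, 2), 7.46)
  expect_equal(round(ev$evalue_ci, 2), 3.06)
  expect_equal(compute_evalue(1)$evalue_point, 1)
  # protective ratio: transform to 1/RR = 2 first, E = 2 + sqrt(2)
  ev2 <- compute_evalue(0.5)
  expect_equal(ev2$evalue_point, 2 + sqrt(2), tolerance = 1e-12)
  expect_match(ev2$note, "1/RR")
  # CI crossing one maps to 1
  expect_equal(compute_evalue(1.5, 0.9, 2.1)$evalue_ci, 1)
  # E >= RR and monotone in RR
  rrs <- seq(1, 6, by = 0.25)
  es <- vapply(rrs, function(r) compute_evalue(r)$evalue_point, 0)
  expect_true(all(es >= rrs))
  expect_true(all(diff(es) > 0))
  expect_error(compute_evalue(-1), "positive")
  expect_error(compute_evalue(2, -1, 3), "positive")
  expect_error(compute_evalue(2, 3, 2), "exceed")
  expect_error(compute_evalue(2, 1.5), "both")
})
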