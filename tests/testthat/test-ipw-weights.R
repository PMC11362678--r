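test_that("randomized exposure yields null denominator coefficients", {
  cfg <- sim_config(n_subjects = 20000, seed = 21,
                    coef_A1 = c("(Intercept)" = qlogis(0.2)),
                    region_sd = c(A1 = 0, A2 = 0.2, haz = 0.1, cens = 0.1))
  co <- generate_cohort(cfg)
  em <- fit_exposure_models(co)
  est <- em$den1$coefficients[-1]
  se <- em$den1$se[-1]
  expect_true(all(abs(est / se) < 3.5))
})

test_that("a single binary confounder's logit coefficients are recovered", {
  # P(A1=1 | L=1) = 0.8, P(A1=1 | L=0) = 0.2:
  # intercept = logit(0.2) = -1.386, slope = logit(0.8)-logit(0.2) = 2.773
  set.seed(31)
  n <- 50000
  co <- data.frame(id = seq_len(n), L = rbinom(n, 1, 0.5))
  co$A1 <- rbinom(n, 1, ifelse(co$L == 1, 0.8, 0.2))
  co$A2 <- rbinom(n, 1, 0.3)
  em <- fit_exposure_models(co, baseline_covars = "L",
                            tv_covars = character())
  b <- em$den1$coefficients
  se <- em$den1$se
  expect_lt(abs(b[["(Intercept)"]] - (-1.386294)), 3 * se[["(Intercept)"]])
  expect_lt(abs(b[["L"]] - 2.772589), 3 * se[["L"]])
  # intercept-only numerator is the logit of the sample proportion
  expect_equal(unname(em$num1$coefficients), qlogis(mean(co$A1)))
})

test_that("stabilized exposure weights follow the probability ratio", {
  # hand-specified models: P_num(A1=1) = 0.5, P_den(A1=1|.) = 0.8
  co <- data.frame(id = 1:2, A1 = c(1, 0), A2 = c(0, 0))
  em <- structure(list(
    den1 = list(coefficients = c("(Intercept)" = qlogis(0.8)), converged = TRUE),
    num1 = list(coefficients = c("(Intercept)" = qlogis(0.5)), converged = TRUE),
    den2 = list(coefficients = c("(Intercept)" = qlogis(0.5), A1 = 0), converged = TRUE),
    num2 = list(coefficients = c("(Intercept)" = qlogis(0.5), A1 = 0), converged = TRUE),
    baseline_covars = character(), tv_covars = character()),
    class = "exposure_models")
  w <- compute_exposure_weights(em, co)
  expect_equal(w$sw_A1[1], 0.5 / 0.8)          # exposed subject
  expect_equal(w$sw_A1[2], 0.5 / 0.2)          # unexposed subject
  expect_equal(w$sw_A2, c(1, 1))               # identical num/den models
})

test_that("identical numerator and denominator designs give unit weights", {
  co <- fixture_cohort(n = 1000)
  em <- fit_exposure_models(co)
  em$den1$coefficients[] <- em$num1$coefficients[["(Intercept)"]]
  em$den1$coefficients[-1] <- 0
  em$den2$coefficients[] <- 0
  em$den2$coefficients[names(em$num2$coefficients)] <- em$num2$coefficients
  w <- compute_exposure_weights(em, co)
  expect_equal(w$sw_A1, rep(1, nrow(co)), tolerance = 1e-12)
  expect_equal(w$sw_A2, rep(1, nrow(co)), tolerance = 1e-12)
})

test_that("untruncated stabilized weights average to one", {
  cfg <- sim_config(n_subjects = 20000, seed = 14)
  co <- generate_cohort(cfg)
  em <- fit_exposure_models(co)
  w <- compute_exposure_weights(em, co)
  expect_gt(mean(w$sw_A1 * w$sw_A2), 0.97)
  expect_lt(mean(w$sw_A1 * w$sw_A2), 1.03)
})

test_that("positivity violations raise a hard error", {
  co <- data.frame(id = 1:3, A1 = c(1, 0, 0), A2 = c(0, 0, 0))
  em <- structure(list(
    den1 = list(coefficients = c("(Intercept)" = -20), converged = TRUE),
    num1 = list(coefficients = c("(Intercept)" = 0), converged = TRUE),
    den2 = list(coefficients = c("(Intercept)" = 0, A1 = 0), converged = TRUE),
    num2 = list(coefficients = c("(Intercept)" = 0, A1 = 0), converged = TRUE),
    baseline_covars = character(), tv_covars = character()),
    class = "exposure_models")
  expect_error(compute_exposure_weights(em, co), "positivity")
})

test_that("censoring weights degenerate to one without censoring events", {
  co <- make_cohort(T = rep(14, 50), event = 0, cause = "")
  py <- expand_person_years(co, K = 14)
  cm <- fit_censoring_models(py)
  expect_true(cm$degenerate)
  w <- compute_censoring_weights(cm, py)
  expect_equal(w$sw_C, rep(1, nrow(py)))
})

test_that("independent constant censoring gives near-unit weights", {
  cfg <- sim_config(n_subjects = 20000, seed = 15,
                    coef_cens = c("(Intercept)" = qlogis(0.05)))
  co <- generate_cohort(cfg)
  py <- expand_person_years(co, 14, "suicide")
  cm <- fit_censoring_models(py)
  w <- compute_censoring_weights(cm, py)
  per_year <- tapply(w$sw_C, py$k, mean)
  expect_true(all(per_year > 0.95 & per_year < 1.05))
})

test_that("the two-period worked example gives the hand-computed weight", {
  # balanced factorial L x A1 x A2 (80 per cell); censoring in year 1
  # with P = 0.5 given L = 1 and 0.25 given L = 0, so the marginal
  # uncensored probability is 0.625 and the stabilized weight of an
  # uncensored L = 1 subject at k = 1 is 0.625 / 0.5 = 1.25 exactly
  cells <- expand.grid(L = 0:1, A1 = 0:1, A2 = 0:1)
  co <- cells[rep(seq_len(8), each = 80), ]
  co$id <- seq_len(nrow(co))
  cens <- unlist(lapply(seq_len(8), function(i) {
    n_c <- if (cells$L[i] == 1) 40 else 20
    c(rep(TRUE, n_c), rep(FALSE, 80 - n_c))
  }))
  co$T <- ifelse(cens, 1L, 2L)
  co$event <- 0L
  co$cause_code <- ""
  py <- expand_person_years(co, K = 2)
  py1 <- py[py$k == 1, ]
  cm <- fit_censoring_models(py1, baseline_covars = "L",
                             tv_covars = character(), time_form = "none")
  w <- compute_censoring_weights(cm, py1)
  swc <- w$sw_C[py1$uncensored == 1 & py1$L == 1]
  expect_equal(unique(round(swc, 10)), 0.625 / 0.5, tolerance = 1e-7)
  swc0 <- w$sw_C[py1$uncensored == 1 & py1$L == 0]
  expect_equal(unique(round(swc0, 10)), 0.625 / 0.75, tolerance = 1e-7)
})

test_that("cumulative censoring weights obey the one-step recursion", {
  cfg <- sim_config(n_subjects = 2000, seed = 16)
  co <- generate_cohort(cfg)
  py <- expand_person_years(co, 14, "suicide")
  cm <- fit_censoring_models(py)
  w <- compute_censoring_weights(cm, py)
  # recompute the per-row ratio from the fitted models and check
  # sw_C(k) = sw_C(k-1) * ratio(k) within subject
  first <- !duplicated(py$id)
  ratio <- numeric(nrow(py))
  ratio[first] <- w$sw_C[first]
  ratio[!first] <- w$sw_C[!first] / w$sw_C[which(!first) - 1L]
  sw_rebuilt <- ave(ratio, py$id, FUN = cumprod)
  expect_equal(sw_rebuilt, w$sw_C, tolerance = 1e-12)
})

test_that("truncation caps at the empirical percentile and is contractive", {
  ws <- structure(list(id = seq_len(1010), sw_A1 = c(rep(1, 1000), rep(50, 10)),
                       sw_A2 = rep(1, 1010), sw_C = NULL, py_id = NULL,
                       thresholds = NULL), class = "weight_set")
  tr <- truncate_weights(ws, percentile = 99)
  thr <- quantile(ws$sw_A1 * ws$sw_A2, 0.99, type = 7, names = FALSE)
  expect_equal(max(tr$sw_A_trunc), thr)
  expect_equal(unname(tr$thresholds$exposure[["upper"]]), thr)
  expect_lte(max(tr$sw_A_trunc), max(ws$sw_A1))
  expect_lte(mean(tr$sw_A_trunc), mean(ws$sw_A1 * ws$sw_A2))
  # all-equal weights are untouched
  ws2 <- structure(list(id = 1:10, sw_A1 = rep(2, 10), sw_A2 = rep(0.5, 10),
                        sw_C = NULL, py_id = NULL, thresholds = NULL),
                   class = "weight_set")
  expect_equal(truncate_weights(ws2)$sw_A_trunc, rep(1, 10))
  expect_error(truncate_weights(ws, percentile = 40), "percentile")
  expect_error(truncate_weights(ws, percentile = 100), "percentile")
})

test_that("final weights are the product of their components", {
  co <- make_cohort(T = c(3, 2), event = c(0, 0), cause = "")
  py <- expand_person_years(co, K = 14)
  # hand-set truncated components: sw_A = 0.8, sw_C(3) = 1.5 -> 1.2
  ws <- structure(list(id = c(1, 2), sw_A1 = c(0.8, 1), sw_A2 = c(1, 1),
                       sw_C = c(1, 1, 1.5, 1, 1), py_id = py$id,
                       sw_A_trunc = c(0.8, 1),
                       sw_C_trunc = c(1, 1, 1.5, 1, 1),
                       thresholds = NULL), class = "weight_set")
  out <- combine_weights(ws, py)
  expect_equal(out$w_final[3], 0.8 * 1.5)  # subject 1, year 3
  expect_equal(out$w_final, c(0.8, 0.8, 1.2, 1, 1))
  bad <- ws
  bad$sw_C_trunc <- c(1, 1)
  expect_error(combine_weights(bad, py), "match")
})

test_that("weighted person-time stays close to observed person-time", {
  cfg <- sim_config(n_subjects = 20000, seed = 22)
  co <- generate_cohort(cfg)
  fit <- msm_pooled(co, target_cause = "suicide")
  py <- expand_person_years(co, 14, "suicide")
  w <- combine_weights(fit$weights, py)
  expect_lt(abs(sum(w$w_final) / nrow(py) - 1), 0.05)
})
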