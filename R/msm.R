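#' Fit the inverse-probability-weighted pooled logistic MSM
#'
#' The package's central model fit. Runs the full estimation sequence on a
#' subject-level cohort: (optional) random-forest imputation of missing
#' covariates, stabilized inverse-probability-of-exposure weights for both
#' waves, cumulative stabilized censoring weights, percentile truncation,
#' the weighted pooled logistic discrete-time hazard model of the target
#' cause on exposure regime and time, counterfactual cumulative-incidence
#' curves under the four joint exposure regimes, and risk
#' difference/ratio contrasts at the requested horizons. Confidence
#' intervals come from [bootstrap_pipeline()]; E-values from
#' [compute_evalue()].
#'
#' @param cohort cohort table (see [read_cohort()] / [generate_cohort()]):
#'   one row per subject with `id`, `region`, baseline covariates, `A1`,
#'   time-varying covariates, `A2`, `T`, `event`, `cause_code`. `A1`,
#'   `A2` and `T` must be complete.
#' @param target_cause `"suicide"`, `"non_suicide"` or `"all_cause"`.
#' @param baseline_covars,tv_covars analysis covariates; defaults use
#'   every recognised covariate column present.
#' @param K follow-up years.
#' @param horizons contrast horizons (default midpoint and end).
#' @param time_form time specification of the hazard model
#'   (`"quadratic"`, `"linear"`, `"categorical"`).
#' @param regime_time include regime-by-time product terms; `FALSE` gives
#'   the parsimonious specification used for stratified re-runs.
#' @param time_form_cens time specification of the censoring models.
#' @param truncation_percentile weight truncation percentile.
#' @param positivity_floor hard error threshold for denominator
#'   probabilities.
#' @param impute_missing impute missing covariates with [rf_impute()]
#'   (skipped automatically when the cohort is complete).
#' @param impute_max_iter,num_trees forwarded to [rf_impute()].
#' @param seed seed for the imputation forests.
#'
#' @return object of class `msm_pooled` with components `cohort` (the
#'   completed analysis table), `exposure_models`, `censoring_models`,
#'   `weights` (a `weight_set`), `hazard_model`, `curves`, `contrasts`,
#'   `diagnostics`, `imputation` (trace or `NULL`) and `settings`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `residuals`.
#' @seealso [bootstrap_pipeline()], [run_analysis()]
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2000, seed = 3)
#' cohort <- generate_cohort(cfg)
#' fit <- msm_pooled(cohort, target_cause = "all_cause")
#' fit
#' predict(fit, regime = "alone-alone", k = 14, type = "risk")
msm_pooled <- function(cohort,
                       target_cause = c("suicide", "non_suicide",
                                        "all_cause"),
                       baseline_covars = NULL, tv_covars = NULL, K = 14L,
                       horizons = NULL,
                       time_form = c("quadratic", "linear", "categorical"),
                       regime_time = TRUE,
                       time_form_cens = c("quadratic", "linear", "none"),
                       truncation_percentile = 99, positivity_floor = 1e-6,
                       impute_missing = TRUE, impute_max_iter = 10L,
                       num_trees = 100L, seed = 1L) {
  target_cause <- match.arg(target_cause)
  time_form <- match.arg(time_form)
  time_form_cens <- match.arg(time_form_cens)
  if (is.null(horizons)) horizons <- unique(c(ceiling(K / 2), K))
  if (is.null(baseline_covars)) baseline_covars <- .default_baseline_covars(cohort)
  if (is.null(tv_covars)) tv_covars <- .default_tv_covars(cohort)
  if (anyNA(cohort$A1) || anyNA(cohort$A2) || anyNA(cohort$T))
    stop("A1, A2 and T must be complete; read_cohort() drops such subjects")

  imputation <- NULL
  covars <- unique(c(baseline_covars, tv_covars))
  if (anyNA(cohort[, covars])) {
    if (!impute_missing)
      stop("cohort has missing covariates and impute_missing = FALSE")
    imp <- rf_impute(cohort, max_iter = impute_max_iter,
                     num_trees = num_trees, seed = seed)
    cohort <- imp$completed
    imputation <- imp[c("n_iterations", "divergence_trace", "seed")]
  }

  em <- fit_exposure_models(cohort, baseline_covars, tv_covars)
  w <- compute_exposure_weights(em, cohort, positivity_floor)
  py <- expand_person_years(cohort, K = K, target_cause = target_cause)
  cm <- fit_censoring_models(py, baseline_covars, tv_covars,
                             time_form = time_form_cens)
  w <- compute_censoring_weights(cm, py, weights = w,
                                 positivity_floor = positivity_floor)
  w <- truncate_weights(w, percentile = truncation_percentile)
  py <- combine_weights(w, py)
  hm <- fit_pooled_logistic(py, weights = py$w_final, time_form = time_form,
                            regime_time = regime_time)
  curves <- build_regime_curves(hm, K = K, se = TRUE)
  contrasts <- compute_contrasts(curves, horizons = horizons)
  diagnostics <- list(
    n_subjects = nrow(cohort),
    n_person_years = nrow(py),
    n_events = sum(py$event),
    n_lost = sum(py$uncensored == 0),
    weights = weight_diagnostics(w))
  structure(list(
    call = match.call(), cohort = cohort, exposure_models = em,
    censoring_models = cm, weights = w, hazard_model = hm,
    curves = curves, contrasts = contrasts, diagnostics = diagnostics,
    imputation = imputation,
    settings = list(target_cause = target_cause,
                    baseline_covars = baseline_covars,
                    tv_covars = tv_covars, K = as.integer(K),
                    horizons = horizons, time_form = time_form,
                    regime_time = regime_time,
                    time_form_cens = time_form_cens,
                    truncation_percentile = truncation_percentile,
                    positivity_floor = positivity_floor, seed = seed)),
    class = "msm_pooled")
}

#' @export
print.msm_pooled <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Weighted pooled logistic MSM — target cause: %s\n",
              s$target_cause))
  cat(sprintf("%d subjects, %d person-years, %d events, %d lost to follow-up\n",
              x$diagnostics$n_subjects, x$diagnostics$n_person_years,
              x$diagnostics$n_events, x$diagnostics$n_lost))
  K <- s$K
  at_end <- as.data.frame(x$curves)[x$curves$k == K, c("regime", "cuminc")]
  cat(sprintf("Counterfactual cumulative incidence at %d years:\n", K))
  print(at_end, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.msm_pooled <- function(object, ...) {
  structure(list(settings = object$settings,
                 diagnostics = object$diagnostics,
                 coefficients = cbind(
                   estimate = object$hazard_model$coefficients,
                   robust_se = object$hazard_model$se_robust),
                 contrasts = object$contrasts,
                 imputation = object$imputation),
            class = "summary.msm_pooled")
}

#' @export
print.summary.msm_pooled <- function(x, ...) {
  cat(sprintf("Weighted pooled logistic MSM — target cause: %s\n\n",
              x$settings$target_cause))
  cat("Hazard model coefficients (robust SEs are diagnostics; use the bootstrap for CIs):\n")
  print(round(x$coefficients, 4))
  cat("\nWeight diagnostics (untruncated stabilized weights should average ~1):\n")
  print(x$diagnostics$weights, row.names = FALSE, digits = 4)
  cat("\nContrasts vs the doubly-unexposed reference regime:\n")
  print(x$contrasts, row.names = FALSE, digits = 3)
  if (!is.null(x$imputation))
    cat(sprintf("\nCovariate imputation: %d random-forest sweep(s)\n",
                x$imputation$n_iterations))
  invisible(x)
}

#' @export
coef.msm_pooled <- function(object, ...) object$hazard_model$coefficients

#' Predict hazards, risks or survival from a fitted MSM
#'
#' @param object fitted [msm_pooled()] model.
#' @param regime regime label or `c(a1, a2)` vector.
#' @param k year(s) within 1..K.
#' @param type `"hazard"` (yearly discrete hazard), `"risk"` (cumulative
#'   incidence) or `"survival"`.
#' @param ... unused.
#' @export
predict.msm_pooled <- function(object, regime, k,
                               type = c("hazard", "risk", "survival"),
                               ...) {
  type <- match.arg(type)
  if (type == "hazard") return(predict_hazard(object$hazard_model, regime, k))
  if (any(k < 1 | k > object$settings$K))
    stop(sprintf("year index outside 1..%d", object$settings$K))
  lab <- .REGIME_LABELS[[paste0(.parse_regime(regime), collapse = "")]]
  cc <- object$curves[object$curves$regime == lab, ]
  v <- if (type == "risk") cc$cuminc else cc$surv
  v[k]
}

#' @export
residuals.msm_pooled <- function(object, type = c("pearson", "response"),
                                 ...) {
  type <- match.arg(type)
  py <- expand_person_years(object$cohort, K = object$settings$K,
                            target_cause = object$settings$target_cause)
  h <- plogis(drop(
    .regime_design(py$A1, py$A2, py$k, object$settings$K,
                   object$hazard_model$time_form, TRUE,
                   object$hazard_model$regime_time) %*%
      object$hazard_model$coefficients))
  r <- py$event - h
  if (type == "pearson") r <- r / sqrt(h * (1 - h))
  r
}

#' Plot counterfactual cumulative-incidence curves
#'
#' One curve per joint exposure regime, optionally with pointwise
#' bootstrap bands.
#'
#' @param x fitted [msm_pooled()] model.
#' @param boot optional [bootstrap_pipeline()] result; adds dashed
#'   percentile bands.
#' @param ... forwarded to [graphics::matplot()].
#' @export
plot.msm_pooled <- function(x, boot = NULL, ...) {
  K <- x$settings$K
  labs <- unname(.REGIME_LABELS)
  Fm <- sapply(labs, function(r) x$curves$cuminc[x$curves$regime == r])
  matplot(seq_len(K), Fm, type = "s", lty = 1, lwd = 2, col = 1:4,
          xlab = "Years of follow-up", ylab = "Cumulative incidence",
          main = sprintf("Counterfactual cumulative incidence (%s)",
                         x$settings$target_cause), ...)
  if (!is.null(boot)) {
    for (i in seq_along(labs)) {
      ci <- boot$curve_ci[boot$curve_ci$regime == labs[i], ]
      graphics::lines(ci$k, ci$cuminc_lower, lty = 2, col = i)
      graphics::lines(ci$k, ci$cuminc_upper, lty = 2, col = i)
    }
  }
  legend("topleft", legend = labs, col = 1:4, lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
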