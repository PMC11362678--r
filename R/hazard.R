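# Person-period expansion, the weighted pooled logistic discrete-time
# hazard model, and the Kaplan-Meier diagnostic comparator.

#' Expand a cohort into discrete person-years
#'
#' Subject i contributes `T_i` one-year rows (k = 1..T_i). The event
#' indicator is 1 only in the terminal row of subjects whose follow-up
#' ended in the target cause (for `"all_cause"`, any death). Deaths from
#' non-target causes end follow-up with `event = 0` (cause-specific
#' censoring of the target cause). Loss to follow-up (`event = 0`,
#' `T < K`) ends the contribution with `event = 0` and marks the terminal
#' row `uncensored = 0`, the indicator the censoring-weight models are fit
#' on; competing-cause deaths are not treated as loss to follow-up.
#'
#' @param cohort cohort table with `T`, `event`, `cause_code`.
#' @param K follow-up length in years.
#' @param target_cause `"suicide"`, `"non_suicide"` or `"all_cause"`.
#' @return `data.frame` of class `person_year_table`: subject columns
#'   (id, region, covariates, `A1`, `A2`) replicated per year, plus `k`,
#'   `event` and `uncensored`. Attributes `K` and `target_cause`.
#' @export
expand_person_years <- function(cohort, K = 14L,
                                target_cause = c("suicide", "non_suicide",
                                                 "all_cause")) {
  target_cause <- match.arg(target_cause)
  Tv <- cohort$T
  if (!is.numeric(Tv)) stop("follow-up column T must be numeric")
  bad <- which(Tv < 1 | Tv > K | Tv != round(Tv))
  if (length(bad))
    stop(sprintf("invalid follow-up durations (must be integers in 1..%d) for subjects %s%s",
                 K, paste(head(cohort$id[bad], 5), collapse = ", "),
                 if (length(bad) > 5) ", ..." else ""))
  labels <- classify_cause(cohort$cause_code)
  target_event <- cohort$event == 1 &
    switch(target_cause,
           suicide = labels == "suicide",
           non_suicide = labels == "non_suicide",
           all_cause = labels != "none")
  lost <- cohort$event == 0 & Tv < K
  Tv <- as.integer(Tv)
  keep <- setdiff(names(cohort), c("T", "event", "cause_code"))
  idx <- rep.int(seq_len(nrow(cohort)), Tv)
  py <- cohort[idx, keep, drop = FALSE]
  rownames(py) <- NULL
  py$k <- sequence(Tv)
  last <- py$k == Tv[idx]
  py$event <- as.integer(last & target_event[idx])
  py$uncensored <- as.integer(!(last & lost[idx]))
  attr(py, "K") <- as.integer(K)
  attr(py, "target_cause") <- target_cause
  class(py) <- c("person_year_table", "data.frame")
  py
}

.regime_design <- function(A1, A2, k, K, time_form, regime_terms,
                           regime_time) {
  n <- length(k)
  cols <- list("(Intercept)" = rep(1, n))
  if (time_form == "categorical") {
    for (j in 2:K) cols[[paste0("k", j)]] <- as.numeric(k == j)
  } else if (time_form != "none") {
    cols$k <- k
    if (time_form == "quadratic") cols$k2 <- k^2
  }
  if (regime_terms) {
    r01 <- as.numeric(A1 == 0 & A2 == 1)
    r10 <- as.numeric(A1 == 1 & A2 == 0)
    r11 <- as.numeric(A1 == 1 & A2 == 1)
    cols$r01 <- r01; cols$r10 <- r10; cols$r11 <- r11
    if (regime_time && time_form %in% c("linear", "quadratic")) {
      cols$`r01:k` <- r01 * k; cols$`r10:k` <- r10 * k
      cols$`r11:k` <- r11 * k
    }
  }
  do.call(cbind, cols)
}

#' Fit the weighted pooled logistic discrete-time hazard model
#'
#' Weighted maximum-likelihood logistic regression of the yearly event
#' indicator on exposure-regime indicators (three indicators against the
#' doubly-unexposed reference regime) and time in years. Time enters as
#' `k + k^2` by default, with regime-by-time product terms; a categorical
#' (saturated) time specification is available for the Kaplan-Meier
#' diagnostic. Point estimates drive all downstream inference; a
#' cluster-robust (by subject) sandwich variance is reported as a
#' diagnostic only — confidence intervals come from the bootstrap.
#'
#' @param person_years a [expand_person_years()] table.
#' @param weights per-row weights; default the `w_final` column if
#'   present, else 1 (unweighted).
#' @param time_form `"quadratic"`, `"linear"`, `"categorical"` (saturated
#'   yearly indicators) or `"none"` (constant hazard).
#' @param regime_terms include the three regime indicators.
#' @param regime_time include regime-by-k product terms (dropped under the
#'   parsimonious specification used for stratified re-runs, and ignored
#'   with categorical or constant time).
#' @return object of class `pooled_logistic` with `coefficients`,
#'   model-based and cluster-robust variance matrices, convergence flag
#'   and the fit specification.
#' @export
fit_pooled_logistic <- function(person_years, weights = NULL,
                                time_form = c("quadratic", "linear",
                                              "categorical", "none"),
                                regime_terms = TRUE, regime_time = TRUE) {
  time_form <- match.arg(time_form)
  K <- attr(person_years, "K") %||% max(person_years$k)
  if (is.null(weights))
    weights <- person_years$w_final %||% rep(1, nrow(person_years))
  if (sum(person_years$event) < 1) stop("no events in person-year table")
  if (regime_terms) {
    cell <- table(factor(paste0(person_years$A1, person_years$A2),
                         levels = c("00", "01", "10", "11")),
                  person_years$event)
    if (ncol(cell) == 2) {
      empty <- rownames(cell)[cell[, "1"] == 0]
      if (length(empty))
        warning(sprintf("zero events in regime cell(s): %s",
                        paste(empty, collapse = ", ")))
    }
  }
  X <- .regime_design(person_years$A1, person_years$A2, person_years$k, K,
                      time_form, regime_terms, regime_time)
  fit <- .logit_fit(X, person_years$event, w = weights,
                    cluster = person_years$id,
                    check_separation = time_form != "categorical",
                    model_name = "pooled logistic hazard model")
  structure(list(coefficients = fit$coefficients, vcov = fit$vcov,
                 vcov_robust = fit$vcov_robust, se_robust = fit$se_robust,
                 converged = fit$converged, K = K, time_form = time_form,
                 regime_terms = regime_terms,
                 regime_time = regime_time &&
                   time_form %in% c("linear", "quadratic"),
                 n_events = sum(person_years$event),
                 n_rows = nrow(person_years)),
            class = "pooled_logistic")
}

#' @export
print.pooled_logistic <- function(x, ...) {
  cat(sprintf("Pooled logistic discrete-time hazard model (%s time%s)\n",
              x$time_form, if (x$regime_time) " + regime x k" else ""))
  cat(sprintf("%d person-years, %d events\n", x$n_rows, x$n_events))
  tab <- cbind(estimate = x$coefficients,
               robust_se = x$se_robust %||% rep(NA_real_, length(x$coefficients)))
  print(round(tab, 4))
  invisible(x)
}

#' Predict the discrete-time hazard under an exposure regime
#'
#' Expit of the fitted linear predictor with the regime indicators and
#' time terms set for the requested regime and year(s). Years outside the
#' fitted range 1..K raise an error (no extrapolation).
#'
#' @param model a [fit_pooled_logistic()] fit.
#' @param regime length-2 0/1 vector `c(a1, a2)` or a label among
#'   `"with-with"`, `"with-alone"`, `"alone-with"`, `"alone-alone"`.
#' @param k year index or vector of years, within 1..K.
#' @return numeric vector of hazards in (0, 1).
#' @export
predict_hazard <- function(model, regime, k) {
  stopifnot(inherits(model, "pooled_logistic"))
  regime <- .parse_regime(regime)
  if (any(k < 1 | k > model$K))
    stop(sprintf("year index outside the fitted range 1..%d; no extrapolation",
                 model$K))
  X <- .regime_design(rep(regime[1], length(k)), rep(regime[2], length(k)),
                      k, model$K, model$time_form, model$regime_terms,
                      model$regime_time)
  X <- X[, names(model$coefficients), drop = FALSE]
  plogis(drop(X %*% model$coefficients))
}

.REGIME_LABELS <- c("00" = "with-with", "01" = "with-alone",
                    "10" = "alone-with", "11" = "alone-alone")

.parse_regime <- function(regime) {
  if (is.character(regime)) {
    key <- names(.REGIME_LABELS)[match(regime, .REGIME_LABELS)]
    if (is.na(key)) key <- if (regime %in% names(.REGIME_LABELS)) regime else NA
    if (is.na(key))
      stop(sprintf("unknown regime label '%s'", regime))
    as.integer(strsplit(key, "")[[1]])
  } else {
    stopifnot(length(regime) == 2, all(regime %in% c(0, 1)))
    as.integer(regime)
  }
}

#' Kaplan-Meier survival on the discrete yearly grid
#'
#' Product-limit estimator (via [survival::survfit()]) of target-cause
#' survival, with the same cause-specific censoring convention as
#' [expand_person_years()]: non-target deaths and loss to follow-up
#' censor at `T`. Serves as the diagnostic comparator for the pooled
#' logistic survival curve.
#'
#' @param cohort cohort table.
#' @param group_by `"none"` for one overall curve or `"regime"` for one
#'   curve per observed joint exposure pattern.
#' @param target_cause as in [expand_person_years()].
#' @param K evaluation grid 1..K.
#' @return `data.frame` with `group`, `k`, `surv`.
#' @export
km_estimate <- function(cohort, group_by = c("none", "regime"),
                        target_cause = c("suicide", "non_suicide",
                                         "all_cause"),
                        K = 14L) {
  group_by <- match.arg(group_by)
  target_cause <- match.arg(target_cause)
  labels <- classify_cause(cohort$cause_code)
  ev <- as.integer(cohort$event == 1 &
    switch(target_cause,
           suicide = labels == "suicide",
           non_suicide = labels == "non_suicide",
           all_cause = labels != "none"))
  grp <- if (group_by == "regime")
    .REGIME_LABELS[paste0(cohort$A1, cohort$A2)] else "all"
  out <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    if (!any(sel)) { warning(sprintf("empty group '%s' omitted", g)); next }
    sf <- survival::survfit(survival::Surv(cohort$T[sel], ev[sel]) ~ 1)
    s <- summary(sf, times = seq_len(K), extend = TRUE)$surv
    out[[g]] <- data.frame(group = g, k = seq_len(K), surv = s)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
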