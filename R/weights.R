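# Stabilized inverse-probability weights for the two exposure waves and
# cumulative stabilized censoring weights, truncated at a percentile and
# combined into the final per-person-year weight.

.default_baseline_covars <- function(cohort)
  intersect(c(.BASELINE_CONT, .BASELINE_BIN), names(cohort))

.default_tv_covars <- function(cohort)
  intersect(c(.TV_BIN, .TV_CONT), names(cohort))

.design <- function(data, covars, extra = NULL, region = TRUE) {
  rhs <- c(extra, covars, if (region && "region" %in% names(data)) "region")
  if (!length(rhs)) rhs <- "1"
  f <- as.formula(paste("~", paste(rhs, collapse = " + ")))
  model.matrix(f, data = data)
}

.check_region_levels <- function(data) {
  if (!"region" %in% names(data) || !is.factor(data$region)) return(data)
  tab <- table(data$region)
  if (any(tab == 0)) {
    warning(sprintf("dropping region level(s) with no subjects: %s",
                    paste(names(tab)[tab == 0], collapse = ", ")))
    data$region <- droplevels(data$region)
  }
  data
}

#' Fit stabilized-weight exposure models for both waves
#'
#' Four maximum-likelihood logistic fits: wave-1 denominator (`A1` on
#' baseline covariates and region fixed effects), wave-1 numerator
#' (intercept only), wave-2 denominator (`A2` on `A1`, baseline and
#' time-varying covariates and region), wave-2 numerator (`A2` on `A1`
#' only). Region enters as indicator variables. Requires a completed
#' cohort (no missing covariates).
#'
#' @param cohort completed cohort table.
#' @param baseline_covars,tv_covars covariate names; defaults use every
#'   recognised covariate column present.
#' @return object of class `exposure_models` (four fits with coefficients,
#'   model-based SEs and convergence flags).
#' @export
fit_exposure_models <- function(cohort, baseline_covars = NULL,
                                tv_covars = NULL) {
  if (is.null(baseline_covars)) baseline_covars <- .default_baseline_covars(cohort)
  if (is.null(tv_covars)) tv_covars <- .default_tv_covars(cohort)
  used <- unique(c(baseline_covars, tv_covars))
  if (anyNA(cohort[, used]))
    stop("cohort has missing covariate values; impute first (rf_impute)")
  if (anyNA(cohort$A1) || anyNA(cohort$A2))
    stop("A1/A2 must not be missing in analysis-ready cohorts")
  cohort <- .check_region_levels(cohort)
  Xd1 <- .design(cohort, baseline_covars)
  den1 <- .logit_fit(Xd1, cohort$A1, model_name = "wave-1 exposure denominator model")
  num1 <- list(coefficients = c("(Intercept)" = qlogis(mean(cohort$A1))),
               converged = TRUE)
  Xd2 <- .design(cohort, c(baseline_covars, tv_covars), extra = "A1")
  den2 <- .logit_fit(Xd2, cohort$A2, model_name = "wave-2 exposure denominator model")
  Xn2 <- .design(cohort, character(), extra = "A1", region = FALSE)
  num2 <- .logit_fit(Xn2, cohort$A2, model_name = "wave-2 exposure numerator model")
  structure(list(den1 = den1, num1 = num1, den2 = den2, num2 = num2,
                 baseline_covars = baseline_covars, tv_covars = tv_covars),
            class = "exposure_models")
}

#' @export
print.exposure_models <- function(x, ...) {
  cat("Stabilized-weight exposure models (logistic):\n")
  cat(sprintf("  wave-1 denominator: %d terms, converged: %s\n",
              length(x$den1$coefficients), x$den1$converged))
  cat(sprintf("  wave-2 denominator: %d terms, converged: %s\n",
              length(x$den2$coefficients), x$den2$converged))
  invisible(x)
}

.prob_of_observed <- function(p1, a) a * p1 + (1 - a) * (1 - p1)

.positivity_check <- function(p, floor, what, ids) {
  bad <- which(p < floor)
  if (length(bad))
    stop(sprintf("positivity violation in %s: %d probabilit%s below %g (subjects %s%s)",
                 what, length(bad), if (length(bad) == 1) "y" else "ies", floor,
                 paste(head(ids[bad], 5), collapse = ", "),
                 if (length(bad) > 5) ", ..." else ""))
  invisible(TRUE)
}

#' Compute stabilized exposure weights
#'
#' `sw_A1 = P_num(A1 = a1_i) / P_den(A1 = a1_i | L0, region)` and
#' `sw_A2 = P_num(A2 = a2_i | A1_i) / P_den(A2 = a2_i | A1_i, L0, L1,
#' region)`, with probabilities evaluated at the exposure actually
#' received. Untruncated stabilized weights have sample mean close to 1;
#' [weight_diagnostics()] reports this on every run.
#'
#' @param models an [fit_exposure_models()] object.
#' @param cohort the completed cohort the models were fitted on (or new
#'   data with the same columns).
#' @param positivity_floor denominator probabilities below this trigger an
#'   error (never silent clipping).
#' @return object of class `weight_set` with per-subject `sw_A1`, `sw_A2`,
#'   the subject `id`s, and empty censoring slots.
#' @export
compute_exposure_weights <- function(models, cohort,
                                     positivity_floor = 1e-6) {
  stopifnot(inherits(models, "exposure_models"))
  cohort <- .check_region_levels(cohort)
  Xd1 <- .design(cohort, models$baseline_covars)
  p1 <- plogis(drop(Xd1 %*% models$den1$coefficients))
  pd1 <- .prob_of_observed(p1, cohort$A1)
  .positivity_check(pd1, positivity_floor, "wave-1 exposure denominator", cohort$id)
  pn1 <- .prob_of_observed(plogis(models$num1$coefficients[["(Intercept)"]]),
                           cohort$A1)
  Xd2 <- .design(cohort, c(models$baseline_covars, models$tv_covars), extra = "A1")
  p2 <- plogis(drop(Xd2 %*% models$den2$coefficients))
  pd2 <- .prob_of_observed(p2, cohort$A2)
  .positivity_check(pd2, positivity_floor, "wave-2 exposure denominator", cohort$id)
  Xn2 <- .design(cohort, character(), extra = "A1", region = FALSE)
  pn2 <- .prob_of_observed(plogis(drop(Xn2 %*% models$num2$coefficients)),
                           cohort$A2)
  structure(list(id = cohort$id, sw_A1 = unname(pn1 / pd1),
                 sw_A2 = unname(pn2 / pd2),
                 sw_C = NULL, py_id = NULL, thresholds = NULL),
            class = "weight_set")
}

#' Fit stabilized censoring-weight models
#'
#' Two pooled logistic fits of the per-year remaining-uncensored
#' indicator: the denominator on time, both exposures, covariates and
#' region; the numerator on time and both exposures only (the numerator
#' may condition on the exposure history because the marginal structural
#' model does). Time enters as `k` plus `k^2` by default. When the table
#' contains no censoring events at all, a degenerate flag is returned and
#' all censoring weights default to 1.
#'
#' @param person_years table from [expand_person_years()] with an
#'   `uncensored` indicator.
#' @param baseline_covars,tv_covars covariates for the denominator model.
#' @param time_form `"quadratic"` (k + k^2), `"linear"`, or `"none"`.
#' @return object of class `censoring_models`.
#' @export
fit_censoring_models <- function(person_years, baseline_covars = NULL,
                                 tv_covars = NULL,
                                 time_form = c("quadratic", "linear", "none")) {
  time_form <- match.arg(time_form)
  if (is.null(baseline_covars)) baseline_covars <- .default_baseline_covars(person_years)
  if (is.null(tv_covars)) tv_covars <- .default_tv_covars(person_years)
  if (all(person_years$uncensored == 1)) {
    return(structure(list(degenerate = TRUE, time_form = time_form,
                          baseline_covars = baseline_covars,
                          tv_covars = tv_covars),
                     class = "censoring_models"))
  }
  tt <- switch(time_form, quadratic = c("k", "I(k^2)"), linear = "k",
               none = character())
  Xd <- .design(person_years, c(baseline_covars, tv_covars),
                extra = c(tt, "A1", "A2"))
  den <- .logit_fit(Xd, person_years$uncensored,
                    model_name = "censoring denominator model")
  Xn <- .design(person_years, character(), extra = c(tt, "A1", "A2"),
                region = FALSE)
  num <- .logit_fit(Xn, person_years$uncensored,
                    model_name = "censoring numerator model")
  structure(list(degenerate = FALSE, den = den, num = num,
                 time_form = time_form, baseline_covars = baseline_covars,
                 tv_covars = tv_covars),
            class = "censoring_models")
}

#' Compute cumulative stabilized censoring weights
#'
#' `sw_C(k) = prod_{j <= k} P_num(uncensored at j | .) / P_den(uncensored
#' at j | .)`, accumulated within subject over the follow-up years. The
#' ratio is evaluated at remaining uncensored regardless of the observed
#' indicator, so the cumulative stabilized weight varies over follow-up.
#'
#' @param models a [fit_censoring_models()] object (possibly degenerate).
#' @param person_years the person-year table the weights are for (rows
#'   ordered by subject and year, as produced by [expand_person_years()]).
#' @param weights optional `weight_set` (from
#'   [compute_exposure_weights()]) whose censoring slots are filled;
#'   otherwise a censoring-only `weight_set` is returned.
#' @param positivity_floor hard error threshold for denominator
#'   probabilities.
#' @return the `weight_set` with `sw_C` (one value per person-year row)
#'   and `py_id` filled.
#' @export
compute_censoring_weights <- function(models, person_years, weights = NULL,
                                      positivity_floor = 1e-6) {
  stopifnot(inherits(models, "censoring_models"))
  n_row <- nrow(person_years)
  if (models$degenerate) {
    sw_C <- rep(1, n_row)
  } else {
    tt <- switch(models$time_form, quadratic = c("k", "I(k^2)"),
                 linear = "k", none = character())
    Xd <- .design(person_years, c(models$baseline_covars, models$tv_covars),
                  extra = c(tt, "A1", "A2"))
    pd <- plogis(drop(Xd %*% models$den$coefficients))
    .positivity_check(pd, positivity_floor, "censoring denominator",
                      person_years$id)
    Xn <- .design(person_years, character(), extra = c(tt, "A1", "A2"),
                  region = FALSE)
    pn <- plogis(drop(Xn %*% models$num$coefficients))
    sw_C <- unname(.group_cumprod(pn / pd, person_years$id))
  }
  if (is.null(weights)) {
    weights <- structure(list(id = unique(person_years$id), sw_A1 = NULL,
                              sw_A2 = NULL, sw_C = NULL, py_id = NULL,
                              thresholds = NULL),
                         class = "weight_set")
  }
  weights$sw_C <- sw_C
  weights$py_id <- person_years$id
  weights
}

# Cumulative product within consecutive runs of `group` (log-cumsum trick).
.group_cumprod <- function(x, group) {
  n <- length(x)
  lg <- cumsum(log(x))
  first <- which(c(TRUE, group[-1] != group[-n]))
  run_len <- diff(c(first, n + 1L))
  offset <- rep.int(c(0, lg[first[-1] - 1L]), run_len)
  exp(lg - offset)
}

#' Truncate stabilized weights at a percentile
#'
#' Caps each weight family at its own empirical percentile (linear
#' interpolation, type 7 — fixed so thresholds are reproducible): the
#' exposure weights as the product `sw_A1 * sw_A2`, the censoring weights
#' per person-year on the cumulative `sw_C`. Upper tail only by default;
#' `scope = "component"` truncates `sw_A1` and `sw_A2` separately, and
#' `two_sided = TRUE` additionally floors at the symmetric lower
#' percentile.
#'
#' @param weights a `weight_set`.
#' @param percentile truncation percentile, in (50, 100).
#' @param scope `"product"` or `"component"` for the exposure part.
#' @param two_sided also truncate the lower tail.
#' @return the `weight_set` with `sw_A_trunc`, `sw_C_trunc` and
#'   `thresholds` filled.
#' @export
truncate_weights <- function(weights, percentile = 99,
                             scope = c("product", "component"),
                             two_sided = FALSE) {
  stopifnot(inherits(weights, "weight_set"))
  scope <- match.arg(scope)
  if (percentile <= 50 || percentile >= 100)
    stop("truncation percentile must lie in (50, 100)")
  cap <- function(x) {
    hi <- quantile(x, percentile / 100, type = 7, names = FALSE)
    lo <- if (two_sided) quantile(x, 1 - percentile / 100, type = 7,
                                  names = FALSE) else -Inf
    list(x = pmin(pmax(x, lo), hi), hi = hi,
         lo = if (two_sided) lo else NA_real_)
  }
  thresholds <- list(percentile = percentile, scope = scope)
  if (!is.null(weights$sw_A1)) {
    if (scope == "product") {
      r <- cap(weights$sw_A1 * weights$sw_A2)
      weights$sw_A_trunc <- r$x
      thresholds$exposure <- c(upper = r$hi, lower = r$lo)
    } else {
      r1 <- cap(weights$sw_A1); r2 <- cap(weights$sw_A2)
      weights$sw_A_trunc <- r1$x * r2$x
      thresholds$exposure <- c(upper_A1 = r1$hi, upper_A2 = r2$hi,
                               lower_A1 = r1$lo, lower_A2 = r2$lo)
    }
  }
  if (!is.null(weights$sw_C)) {
    r <- cap(weights$sw_C)
    weights$sw_C_trunc <- r$x
    thresholds$censoring <- c(upper = r$hi, lower = r$lo)
  }
  weights$thresholds <- thresholds
  weights
}

#' Combine truncated weights into final person-year weights
#'
#' `w_final(k)` is the product of the (truncated) stabilized exposure
#' weight of the subject and the (truncated) cumulative censoring weight
#' of the person-year row. The censoring component may be all ones
#' (degenerate censoring models).
#'
#' @param weights a truncated `weight_set` (see [truncate_weights()]).
#' @param person_years the person-year table the weights belong to.
#' @return `person_years` with a `w_final` column attached.
#' @export
combine_weights <- function(weights, person_years) {
  stopifnot(inherits(weights, "weight_set"))
  if (is.null(weights$sw_A_trunc))
    stop("exposure weights missing or untruncated; call truncate_weights() first")
  swc <- weights$sw_C_trunc
  if (is.null(swc)) swc <- rep(1, nrow(person_years))
  if (length(swc) != nrow(person_years))
    stop(sprintf("censoring weight length (%d) does not match person-year rows (%d)",
                 length(swc), nrow(person_years)))
  m <- match(person_years$id, weights$id)
  if (anyNA(m))
    stop("person-year table contains subjects without exposure weights")
  person_years$w_final <- weights$sw_A_trunc[m] * swc
  person_years
}

#' Weight diagnostics
#'
#' Summary of each stabilized weight family: mean (should be near 1 for
#' untruncated stabilized weights on correctly specified models), SD,
#' range, 99th percentile, and the number of values truncated.
#'
#' @param weights a `weight_set`.
#' @return `data.frame` with one row per weight family.
#' @export
weight_diagnostics <- function(weights) {
  stopifnot(inherits(weights, "weight_set"))
  row <- function(name, x, trunc_x = NULL) {
    data.frame(family = name, n = length(x), mean = mean(x), sd = sd_(x),
               min = min(x), max = max(x),
               p99 = quantile(x, 0.99, type = 7, names = FALSE),
               n_truncated = if (is.null(trunc_x)) NA_integer_
                             else sum(trunc_x < x))
  }
  sd_ <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  out <- list()
  if (!is.null(weights$sw_A1)) {
    out$a1 <- row("sw_A1 (untruncated)", weights$sw_A1)
    out$a2 <- row("sw_A2 (untruncated)", weights$sw_A2)
    prod_w <- weights$sw_A1 * weights$sw_A2
    out$prod <- row("sw_A1*sw_A2", prod_w, weights$sw_A_trunc)
  }
  if (!is.null(weights$sw_C))
    out$c <- row("sw_C (cumulative)", weights$sw_C, weights$sw_C_trunc)
  do.call(rbind, out)
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Stabilized weight set\n")
  print(weight_diagnostics(x), row.names = FALSE, digits = 4)
  invisible(x)
}
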