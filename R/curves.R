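# Counterfactual cumulative-incidence curves, risk contrasts, and the
# E-value sensitivity analysis.

#' Counterfactual curves for the four exposure regimes
#'
#' For each joint regime (a1, a2) the hazards h(k) come from
#' [predict_hazard()], survival is the exact product
#' `S(k) = prod_{j<=k} (1 - h(j))` (no exponential approximation) and the
#' cumulative incidence is `F(k) = 1 - S(k)`.
#'
#' @param model a [fit_pooled_logistic()] fit with regime terms.
#' @param K horizon; defaults to the fitted range.
#' @param se also compute pointwise delta-method standard errors of
#'   `F(k)` from the cluster-robust variance (diagnostic; bootstrap
#'   percentiles are the inferential interval).
#' @return `data.frame` of class `regime_curves`: `regime`, `k`, `h`,
#'   `surv`, `cuminc` (and `se` when requested).
#' @export
build_regime_curves <- function(model, K = model$K, se = FALSE) {
  stopifnot(inherits(model, "pooled_logistic"))
  if (!model$regime_terms)
    stop("model was fitted without regime terms; refit with regime_terms = TRUE")
  out <- list()
  for (key in names(.REGIME_LABELS)) {
    a <- as.integer(strsplit(key, "")[[1]])
    k <- seq_len(K)
    h <- predict_hazard(model, a, k)
    S <- cumprod(1 - h)
    d <- data.frame(regime = .REGIME_LABELS[[key]], k = k, h = h,
                    surv = S, cuminc = 1 - S)
    if (se) d$se <- .curve_se(model, a, K)
    out[[key]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("regime_curves", "data.frame")
  attr(res, "K") <- K
  res
}

# Delta-method SE of F(k) under one regime, using the cluster-robust
# variance: dF(k)/dbeta = sum_{j<=k} [prod_{l<=k, l!=j} (1-h_l)] h_j(1-h_j) x_j.
.curve_se <- function(model, regime, K) {
  k <- seq_len(K)
  X <- .regime_design(rep(regime[1], K), rep(regime[2], K), k, model$K,
                      model$time_form, model$regime_terms, model$regime_time)
  X <- X[, names(model$coefficients), drop = FALSE]
  h <- plogis(drop(X %*% model$coefficients))
  S <- cumprod(1 - h)
  V <- model$vcov_robust
  se <- numeric(K)
  grad <- numeric(ncol(X))
  for (kk in k) {
    # gradient accumulates as S(k) * sum_{j<=k} h_j x_j / (1 - h_j) * (1-h_j) adj
    w_j <- S[kk] * h[seq_len(kk)]  # S(k)/(1-h_j) * h_j (1-h_j) = S(k) h_j
    grad <- drop(crossprod(X[seq_len(kk), , drop = FALSE], w_j))
    se[kk] <- sqrt(drop(grad %*% V %*% grad))
  }
  se
}

#' @export
print.regime_curves <- function(x, ...) {
  K <- attr(x, "K") %||% max(x$k)
  cat(sprintf("Counterfactual cumulative incidence (K = %d):\n", K))
  d <- as.data.frame(x)[x$k == K, c("regime", "cuminc")]
  print(d, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Risk differences and risk ratios at chosen horizons
#'
#' Contrasts each regime's cumulative incidence against the
#' doubly-unexposed reference regime (`"with-with"`). Risk differences
#' are reported in percentage points; when the reference risk is zero the
#' risk ratio is undefined and reported as `NA` with a warning.
#'
#' @param curves a [build_regime_curves()] table.
#' @param horizons years at which to contrast (default the midpoint and
#'   the end of a 14-year follow-up).
#' @return `data.frame`: `regime`, `horizon`, `cuminc`, `cuminc_ref`,
#'   `rd_pp` (percentage points), `rr`.
#' @export
compute_contrasts <- function(curves, horizons = c(7, 14)) {
  K <- attr(curves, "K") %||% max(curves$k)
  if (any(horizons < 1 | horizons > K))
    stop(sprintf("horizons must lie within 1..%d", K))
  ref_label <- .REGIME_LABELS[["00"]]
  out <- list()
  for (h in horizons) {
    at <- curves[curves$k == h, ]
    f_ref <- at$cuminc[at$regime == ref_label]
    if (f_ref == 0)
      warning(sprintf("reference risk is 0 at horizon %d; RR undefined (NA)", h))
    for (r in setdiff(unname(.REGIME_LABELS), ref_label)) {
      f <- at$cuminc[at$regime == r]
      rr <- if (f_ref > 0) f / f_ref else NA_real_
      out[[paste(r, h)]] <- data.frame(regime = r, horizon = h, cuminc = f,
                                       cuminc_ref = f_ref,
                                       rd_pp = 100 * (f - f_ref), rr = rr)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' E-value for unmeasured confounding
#'
#' Minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both exposure and outcome —
#' above and beyond the adjusted covariates — to explain away an observed
#' risk ratio: `E = RR + sqrt(RR * (RR - 1))` for `RR >= 1`; ratios below
#' 1 are first inverted. The confidence-interval E-value applies the same
#' formula to the CI limit closer to the null and equals 1 when the CI
#' crosses 1.
#'
#' @param rr observed risk ratio (> 0).
#' @param ci_lower,ci_upper optional 95% CI bounds (positive,
#'   `ci_lower <= ci_upper`).
#' @return object of class `evalue`: `rr_input`, `evalue_point`,
#'   `evalue_ci` (`NA` when no CI given) and a transformation `note` when
#'   the input ratio was below 1.
#' @export
#' @examples
#' compute_evalue(4.00, 1.83, 7.41)  # E-value 7.46, CI E-value 3.06
compute_evalue <- function(rr, ci_lower = NULL, ci_upper = NULL) {
  if (!is.numeric(rr) || length(rr) != 1 || !is.finite(rr) || rr <= 0)
    stop("rr must be a single positive number")
  has_ci <- !is.null(ci_lower) || !is.null(ci_upper)
  if (has_ci) {
    if (is.null(ci_lower) || is.null(ci_upper))
      stop("supply both ci_lower and ci_upper or neither")
    if (!is.finite(ci_lower) || !is.finite(ci_upper) ||
        ci_lower <= 0 || ci_upper <= 0)
      stop("CI bounds must be positive")
    if (ci_lower > ci_upper) stop("ci_lower must not exceed ci_upper")
  }
  ev <- function(r) r + sqrt(r * (r - 1))
  note <- NULL
  if (rr < 1) note <- "input RR below 1; E-value computed on 1/RR"
  e_point <- if (rr >= 1) ev(rr) else ev(1 / rr)
  e_ci <- NA_real_
  if (has_ci) {
    if (ci_lower <= 1 && ci_upper >= 1) {
      e_ci <- 1
    } else if (rr >= 1) {
      e_ci <- ev(ci_lower)
    } else {
      e_ci <- ev(1 / ci_upper)
    }
  }
  structure(list(rr_input = rr, evalue_point = e_point, evalue_ci = e_ci,
                 note = note),
            class = "evalue")
}

#' @export
print.evalue <- function(x, ...) {
  cat(sprintf("E-value: %.2f (point, RR = %.2f)", x$evalue_point, x$rr_input))
  if (!is.na(x$evalue_ci)) cat(sprintf(", %.2f (CI limit)", x$evalue_ci))
  cat("\n")
  if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}
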