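#' Weighted logistic regression via iteratively reweighted least squares
#'
#' Internal fitting engine used by all logistic models in the package
#' (exposure, censoring and pooled hazard models). Solves the weighted
#' maximum-likelihood problem by IRLS with the normal equations formed in
#' compiled code, which keeps the per-replicate cost of the bootstrap low.
#' Coefficients match [stats::glm()] with `family = binomial()` to
#' numerical precision.
#'
#' @param X numeric model matrix (including intercept column).
#' @param y 0/1 response vector.
#' @param w optional non-negative case weights.
#' @param start optional starting coefficient vector (warm start).
#' @param cluster optional cluster id per row; when supplied a
#'   cluster-robust (sandwich) variance is returned alongside the
#'   model-based one.
#' @param compute_vcov compute variance matrices (skipped inside the
#'   bootstrap where only point estimates are needed).
#' @param check_separation error when a coefficient diverges, the usual
#'   symptom of perfect separation. Disable for deliberately saturated
#'   fits (e.g. categorical-time hazard models with zero-event years).
#' @param model_name label used in error messages.
#'
#' @return list with `coefficients` (named), `converged`, `iter`,
#'   `fitted`, and when requested `vcov` (inverse Fisher information) and
#'   `vcov_robust` (sandwich, clustered if `cluster` given) plus `se`.
#' @keywords internal
.logit_fit <- function(X, y, w = NULL, start = NULL, cluster = NULL,
                       compute_vcov = TRUE, check_separation = TRUE,
                       model_name = "logistic model") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  if (length(y) != n || length(w) != n)
    stop(sprintf("%s: response/weight length does not match design matrix", model_name))
  if (is.null(start)) start <- numeric(p)
  fit <- .irls_cpp(X, as.numeric(y), as.numeric(w), as.numeric(start))
  beta <- drop(fit$coefficients)
  names(beta) <- colnames(X)
  if (!fit$converged)
    stop(sprintf("%s did not converge after %d IRLS iterations", model_name, fit$iter))
  if (check_separation && any(abs(beta) > 15)) {
    bad <- names(beta)[abs(beta) > 15]
    stop(sprintf("%s: possible separation, diverging terms: %s",
                 model_name, paste(bad, collapse = ", ")))
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  out <- list(coefficients = beta, converged = fit$converged, iter = fit$iter,
              fitted = mu)
  if (compute_vcov) {
    wm <- pmax(w * mu * (1 - mu), 1e-12)
    info <- crossprod(X * sqrt(wm))
    V <- tryCatch(solve(info), error = function(e) {
      warning(sprintf("%s: singular information matrix, using pseudo-inverse", model_name))
      MASS_ginv(info)
    })
    dimnames(V) <- list(colnames(X), colnames(X))
    out$vcov <- V
    sc <- X * (w * (y - mu))
    if (!is.null(cluster)) sc <- rowsum(sc, group = cluster, reorder = FALSE)
    meat <- crossprod(sc)
    out$vcov_robust <- V %*% meat %*% V
    dimnames(out$vcov_robust) <- dimnames(V)
    out$se <- sqrt(diag(V))
    out$se_robust <- sqrt(diag(out$vcov_robust))
  }
  out
}

# Moore-Penrose inverse via SVD; avoids importing MASS for one corner case.
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
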