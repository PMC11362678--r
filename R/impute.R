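# Iterative random-forest imputation of missing covariates. Follows the
# missForest scheme: initialise missing cells with the column mean/mode,
# then cycle through incomplete variables in order of increasing
# missingness, regressing each on all other predictors with a random
# forest and re-predicting its missing cells, until the set-level change
# statistic first increases (return the previous sweep) or max_iter is
# reached. Exposures and follow-up variables are never imputed.

#' Random-forest imputation of missing covariates
#'
#' Imputes missing covariate cells with an iterative random-forest scheme
#' (Stekhoven-Buehlmann style). Columns listed in `excluded_columns` are
#' never imputed and, with the exception of `cause_code`, must be fully
#' observed — subjects with missing exposure or follow-up information are
#' expected to have been dropped beforehand (see [read_cohort()]).
#' Predictors for each forest are all columns other than `id` and
#' `cause_code` (exposures, region and follow-up variables are retained as
#' predictors so that imputed covariates keep their associations with
#' them). Columns with at most two distinct observed values are treated as
#' categorical and imputed by classification forests; remaining numeric
#' columns use regression forests, whose predictions are averages of
#' observed leaves and therefore stay inside the observed range.
#'
#' The stopping statistic is the missForest delta: for the continuous
#' variable set, the sum of squared changes between consecutive sweeps
#' normalised by the sum of squares of the current values; for the
#' categorical set, the proportion of imputed cells that changed category.
#' Iteration stops the first time the statistic increases for every
#' variable set present, and the previous sweep's values are returned.
#'
#' @param cohort cohort table, possibly with `NA` covariate cells.
#' @param excluded_columns columns never imputed; must contain `A1`, `A2`,
#'   `T`, `event`, `cause_code`.
#' @param max_iter maximum number of sweeps.
#' @param num_trees trees per forest (missForest default, 100).
#' @param mtry variables tried per split; default `ceiling(sqrt(p))`.
#' @param seed integer seed; identical `(cohort, seed)` give identical
#'   completions.
#'
#' @return object of class `rf_impute`: list with `completed` (the cohort
#'   with no missing cells in imputed columns; originally observed cells
#'   untouched), `n_iterations`, `divergence_trace` (per-sweep change
#'   statistics) and `seed`.
#' @export
rf_impute <- function(cohort,
                      excluded_columns = c("id", "region", "A1", "A2", "T",
                                           "event", "cause_code"),
                      max_iter = 10L, num_trees = 100L, mtry = NULL,
                      seed = 1L) {
  required <- c("A1", "A2", "T", "event", "cause_code")
  if (!all(required %in% excluded_columns))
    stop(sprintf("excluded_columns must contain %s",
                 paste(required, collapse = ", ")))
  excluded_columns <- union(excluded_columns, "id")
  for (nm in setdiff(intersect(excluded_columns, names(cohort)), "cause_code"))
    if (anyNA(cohort[[nm]]))
      stop(sprintf("excluded column '%s' contains missing values; drop those subjects first",
                   nm))
  target_cols <- setdiff(names(cohort), excluded_columns)
  n_miss <- vapply(cohort[target_cols], function(x) sum(is.na(x)), 0L)
  fully_missing <- target_cols[n_miss == nrow(cohort)]
  if (length(fully_missing))
    stop(sprintf("column(s) entirely missing, nothing to learn from: %s",
                 paste(fully_missing, collapse = ", ")))
  impute_cols <- target_cols[n_miss > 0]
  trace <- data.frame(iteration = integer(), delta_continuous = numeric(),
                      delta_categorical = numeric())
  if (!length(impute_cols)) {
    return(structure(list(completed = cohort, n_iterations = 1L,
                          divergence_trace = trace, seed = seed),
                     class = "rf_impute"))
  }
  impute_cols <- impute_cols[order(n_miss[impute_cols])]

  is_cat <- vapply(cohort[impute_cols], function(x) {
    is.factor(x) || is.character(x) ||
      length(unique(x[!is.na(x)])) <= 2
  }, logical(1))
  predictors_all <- setdiff(names(cohort), c("id", "cause_code"))
  miss_idx <- lapply(cohort[impute_cols], function(x) which(is.na(x)))

  work <- cohort
  mode_of <- function(x) {
    tab <- sort(table(x[!is.na(x)]), decreasing = TRUE)
    names(tab)[1]
  }
  for (v in impute_cols) {
    i <- miss_idx[[v]]
    if (is_cat[[v]]) {
      m <- mode_of(work[[v]])
      work[[v]][i] <- if (is.integer(work[[v]])) as.integer(m)
                      else if (is.numeric(work[[v]])) as.numeric(m) else m
    } else {
      work[[v]][i] <- mean(work[[v]], na.rm = TRUE)
    }
  }

  prev <- work
  prev_delta <- c(cont = Inf, cat = Inf)
  n_iter <- 0L
  rf_seed <- seed
  repeat {
    n_iter <- n_iter + 1L
    before <- work
    for (v in impute_cols) {
      i <- miss_idx[[v]]
      obs <- setdiff(seq_len(nrow(work)), i)
      xcols <- setdiff(predictors_all, v)
      xdat <- work[, xcols, drop = FALSE]
      yv <- work[[v]]
      rf_seed <- rf_seed + 1L
      if (is_cat[[v]]) {
        yf <- factor(yv[obs])
        if (nlevels(yf) < 2) {  # effectively constant: keep the mode
          work[[v]][i] <- yv[obs][1]
          next
        }
        fit <- ranger::ranger(x = xdat[obs, , drop = FALSE], y = yf,
                              num.trees = num_trees, mtry = mtry,
                              seed = rf_seed, num.threads = 1)
        pred <- predict(fit, data = xdat[i, , drop = FALSE],
                        num.threads = 1, seed = rf_seed)$predictions
        work[[v]][i] <- if (is.integer(yv)) as.integer(as.character(pred))
                        else if (is.numeric(yv)) as.numeric(as.character(pred))
                        else as.character(pred)
      } else {
        fit <- ranger::ranger(x = xdat[obs, , drop = FALSE], y = yv[obs],
                              num.trees = num_trees, mtry = mtry,
                              seed = rf_seed, num.threads = 1)
        work[[v]][i] <- predict(fit, data = xdat[i, , drop = FALSE],
                                num.threads = 1, seed = rf_seed)$predictions
      }
    }
    cont_cols <- impute_cols[!is_cat[impute_cols]]
    cat_cols <- impute_cols[is_cat[impute_cols]]
    delta <- c(cont = NA_real_, cat = NA_real_)
    if (length(cont_cols)) {
      num <- den <- 0
      for (v in cont_cols) {
        i <- miss_idx[[v]]
        num <- num + sum((work[[v]][i] - before[[v]][i])^2)
        den <- den + sum(work[[v]][i]^2)
      }
      delta["cont"] <- if (den > 0) num / den else 0
    }
    if (length(cat_cols)) {
      chg <- tot <- 0
      for (v in cat_cols) {
        i <- miss_idx[[v]]
        chg <- chg + sum(work[[v]][i] != before[[v]][i])
        tot <- tot + length(i)
      }
      delta["cat"] <- chg / tot
    }
    trace <- rbind(trace, data.frame(iteration = n_iter,
                                     delta_continuous = delta[["cont"]],
                                     delta_categorical = delta[["cat"]]))
    present <- !is.na(delta)
    increased <- all(delta[present] > prev_delta[present])
    if (n_iter > 1L && increased) {
      work <- prev  # stop-by-increase: return the previous sweep
      break
    }
    if (all(delta[present] <= .Machine$double.eps)) break  # converged exactly
    if (n_iter >= max_iter) break
    prev <- work
    prev_delta <- delta
  }
  structure(list(completed = work, n_iterations = n_iter,
                 divergence_trace = trace, seed = seed),
            class = "rf_impute")
}

#' @export
print.rf_impute <- function(x, ...) {
  n_cells <- sum(vapply(x$completed, function(col) sum(is.na(col)), 0L))
  cat(sprintf("Random-forest imputation: %d sweep(s), %d residual NA cells\n",
              x$n_iterations, n_cells))
  if (nrow(x$divergence_trace)) print(x$divergence_trace, row.names = FALSE)
  invisible(x)
}
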