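# Cohort CSV readers/writers, ICD-10 cause classification, configuration
# handling and the full-pipeline orchestrator.

#' Classify an ICD-10 cause-of-death code
#'
#' Codes X60-X84 (intentional self-harm, subcodes such as `"X60.0"`
#' included) classify as `"suicide"`; any other valid ICD-10 code as
#' `"non_suicide"`; an empty string (survivor / no death) as `"none"`.
#' Malformed codes raise an error naming the offending positions, so that
#' suicide and non-suicide deaths always partition the valid death codes.
#'
#' @param icd10_code character vector of codes (empty string allowed).
#' @return character vector: `"suicide"`, `"non_suicide"` or `"none"`.
#' @export
#' @examples
#' classify_cause(c("X60", "X84", "X85", "C34.9", ""))
classify_cause <- function(icd10_code) {
  code <- as.character(icd10_code)
  code[is.na(code)] <- ""
  out <- rep("none", length(code))
  nonempty <- code != ""
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9]+)?$", code[nonempty])
  if (any(!ok)) {
    bad_at <- which(nonempty)[!ok]
    stop(sprintf("malformed ICD-10 code(s) at position(s) %s: %s",
                 paste(head(bad_at, 5), collapse = ", "),
                 paste(head(unique(code[bad_at]), 5), collapse = ", ")))
  }
  num <- as.integer(substr(code[nonempty], 2, 3))
  suicide <- substr(code[nonempty], 1, 1) == "X" & num >= 60 & num <= 84
  out[nonempty] <- ifelse(suicide, "suicide", "non_suicide")
  out
}

#' Read a cohort CSV
#'
#' Reads a subject-level cohort table, normalises missing markers (empty
#' cells and `"NA"`) to `NA`, coerces `region` to a factor, and excludes
#' subjects missing `A1`, `A2` or `T` (exposure and follow-up are never
#' imputed; the count of exclusions is reported). The empty `cause_code`
#' of survivors is kept as `""`, not `NA`.
#'
#' @param path CSV file with a header row; required columns `id`,
#'   `region`, `A1`, `A2`, `T`, `event`, `cause_code` plus covariates.
#' @return cohort `data.frame`; attribute `n_excluded` carries the number
#'   of subjects dropped for missing exposure/follow-up.
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("id", "region", "A1", "A2", "T", "event", "cause_code")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$id))
    stop("duplicate subject ids in cohort file")
  if (!is.numeric(d$T))
    stop("follow-up column T must be numeric")
  keep <- !(is.na(d$A1) | is.na(d$A2) | is.na(d$T))
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message(sprintf("excluded %d subject(s) with missing exposure or follow-up data", n_excl))
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  d$cause_code[is.na(d$cause_code)] <- ""
  d$region <- factor(d$region)
  bad <- d$event == 1 & d$cause_code == ""
  if (any(bad))
    stop(sprintf("event = 1 with empty cause_code for subject(s) %s",
                 paste(head(d$id[bad], 5), collapse = ", ")))
  attr(d, "n_excluded") <- n_excl
  d
}

#' Write a cohort CSV
#'
#' Plain-text counterpart of [read_cohort()]: header row, missing cells
#' written empty, no row names. Identical tables produce byte-identical
#' files.
#'
#' @param cohort cohort table.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the complete sequence: load (or simulate) the cohort,
#' impute missing covariates, estimate stabilized exposure and censoring
#' weights, truncate and combine them, fit the weighted pooled logistic
#' hazard model, build counterfactual curves and contrasts, bootstrap
#' percentile intervals, and compute E-values for the risk ratios.
#' Stratified modes subset the cohort (age threshold or gender) and
#' re-run each stratum with the parsimonious model specification (no
#' regime-by-time product terms). Every stage logs row counts, event
#' counts and seeds as `key=value` messages, and a provenance record
#' sufficient to reproduce the run exactly is returned (and written when
#' `output_dir` is set).
#'
#' @param config named list or path to a YAML file. Recognised fields:
#'   `input_csv` or `sim` (arguments for [sim_config()], plus optional
#'   `inject_missingness = TRUE`), `target_cause`, `K`, `horizons`,
#'   `baseline_covars`, `tv_covars`, `stratify` (`"none"`,
#'   `"age_threshold"`, `"gender"`), `age_threshold` (default 60),
#'   `time_form`, `regime_time`, `parsimonious`, `truncation_percentile`,
#'   `B` (bootstrap replicates; 0 disables), `seed`, `output_dir`.
#' @return object of class `msm_analysis`: per-stratum list of `fit`,
#'   `boot`, `results` (tidy contrast table with CIs and E-values), plus
#'   `provenance`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  g <- function(nm, default) config[[nm]] %||% default
  seed <- g("seed", 1L)
  K <- g("K", 14L)
  target_cause <- g("target_cause", "suicide")
  B <- g("B", 0L)
  horizons <- g("horizons", unique(c(ceiling(K / 2), K)))
  log_kv <- function(...) message(paste(sprintf("%s=%s", names(c(...)), c(...)),
                                        collapse = " "))
  n_excluded <- 0L
  if (!is.null(config$input_csv)) {
    cohort <- read_cohort(config$input_csv)
    n_excluded <- attr(cohort, "n_excluded")
    log_kv(c(stage = "read", file = config$input_csv, n = nrow(cohort),
             excluded = n_excluded))
  } else if (!is.null(config$sim)) {
    sim_args <- config$sim
    inject <- isTRUE(sim_args$inject_missingness)
    sim_args$inject_missingness <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    cohort <- generate_cohort(cfg)
    if (inject) cohort <- inject_missingness(cohort, cfg)
    log_kv(c(stage = "simulate", n = nrow(cohort), seed = cfg$seed))
  } else stop("config must provide input_csv or sim")

  stratify <- g("stratify", "none")
  strata <- switch(stratify,
    none = list(all = rep(TRUE, nrow(cohort))),
    age_threshold = {
      thr <- g("age_threshold", 60)
      setNames(list(cohort$age < thr, cohort$age >= thr),
               c(sprintf("age_lt_%g", thr), sprintf("age_ge_%g", thr)))
    },
    gender = list(female = cohort$male == 0, male = cohort$male == 1),
    stop(sprintf("unknown stratification '%s'", stratify)))
  parsimonious <- isTRUE(g("parsimonious", stratify != "none"))

  out <- list()
  for (snm in names(strata)) {
    sub <- cohort[strata[[snm]], , drop = FALSE]
    log_kv(c(stage = "stratum", name = snm, n = nrow(sub),
             deaths = sum(sub$event)))
    fit <- msm_pooled(sub, target_cause = target_cause,
                      baseline_covars = config$baseline_covars,
                      tv_covars = config$tv_covars, K = K,
                      horizons = horizons,
                      time_form = g("time_form", "quadratic"),
                      regime_time = !parsimonious && isTRUE(g("regime_time", TRUE)),
                      truncation_percentile = g("truncation_percentile", 99),
                      seed = seed)
    log_kv(c(stage = "fit", stratum = snm,
             person_years = fit$diagnostics$n_person_years,
             events = fit$diagnostics$n_events))
    boot <- NULL
    results <- fit$contrasts
    results$rd_lower <- results$rd_upper <- NA_real_
    results$rr_lower <- results$rr_upper <- NA_real_
    results$evalue_point <- vapply(results$rr, function(r)
      if (is.na(r)) NA_real_ else compute_evalue(r)$evalue_point, 0)
    results$evalue_ci <- NA_real_
    if (B >= 2) {
      boot <- bootstrap_pipeline(fit, B = B, seed = seed + 1L,
                                 horizons = horizons)
      log_kv(c(stage = "bootstrap", stratum = snm, B = B,
               failed = boot$n_failed))
      m <- match(paste(results$regime, results$horizon),
                 paste(boot$contrast_ci$regime, boot$contrast_ci$horizon))
      for (col in c("rd_lower", "rd_upper", "rr_lower", "rr_upper"))
        results[[col]] <- boot$contrast_ci[[col]][m]
      results$evalue_ci <- mapply(function(r, lo, hi) {
        if (is.na(r) || is.na(lo) || is.na(hi) || lo <= 0) NA_real_
        else compute_evalue(r, lo, hi)$evalue_ci
      }, results$rr, results$rr_lower, results$rr_upper)
    }
    out[[snm]] <- list(fit = fit, boot = boot, results = results)
  }
  provenance <- list(config = config, seed = seed, K = K,
                     target_cause = target_cause, B = B,
                     n_input = nrow(cohort) + n_excluded,
                     n_analysed = nrow(cohort), n_excluded = n_excluded,
                     strata = names(strata),
                     package_version = as.character(utils::packageVersion("poolmsm")),
                     timestamp = format(Sys.time(), tz = "UTC"))
  res <- structure(list(strata = out, provenance = provenance),
                   class = "msm_analysis")
  if (!is.null(config$output_dir)) .write_analysis(res, config$output_dir)
  res
}

.write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_results <- do.call(rbind, lapply(names(res$strata), function(s)
    cbind(stratum = s, res$strata[[s]]$results)))
  write.csv(all_results, file.path(dir, "results.csv"), row.names = FALSE)
  curves <- do.call(rbind, lapply(names(res$strata), function(s) {
    cv <- res$strata[[s]]$fit$curves
    b <- res$strata[[s]]$boot
    if (!is.null(b)) {
      m <- match(paste(cv$regime, cv$k),
                 paste(b$curve_ci$regime, b$curve_ci$k))
      cv$ci_lower <- b$curve_ci$cuminc_lower[m]
      cv$ci_upper <- b$curve_ci$cuminc_upper[m]
    }
    cbind(stratum = s, cv)
  }))
  write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE)
  weights <- do.call(rbind, lapply(names(res$strata), function(s)
    cbind(stratum = s, res$strata[[s]]$fit$diagnostics$weights)))
  write.csv(weights, file.path(dir, "weight_diagnostics.csv"),
            row.names = FALSE)
  prov <- res$provenance
  prov$timestamp <- NULL       # re-runs must be byte-identical
  prov$config$output_dir <- NULL
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' @export
print.msm_analysis <- function(x, ...) {
  cat(sprintf("Pipeline run — target cause: %s, strata: %s\n",
              x$provenance$target_cause,
              paste(x$provenance$strata, collapse = ", ")))
  for (s in names(x$strata)) {
    cat(sprintf("\nStratum %s:\n", s))
    print(x$strata[[s]]$results, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
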