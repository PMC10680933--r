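#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; at tied times events
#' precede censorings (the standard risk-set convention). Thin wrapper over
#' `survival::survfit` exposing the curve as plain vectors plus an optional
#' probability at a queried horizon.
#'
#' @param times survival times in months (>= 0).
#' @param events event indicators (1 = event, 0 = right-censored).
#' @param horizon_months optional time at which to report `S(t)` (e.g. 120
#'   for a 10-year overall-survival probability).
#' @return An object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `surv`, `n`, and (if requested) `surv_at_horizon`.
#' @examples
#' km_estimate(c(5, 10, 15), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events, horizon_months = NULL) {
  if (length(times) < 1L) data_error("empty survival data")
  if (any(times < 0)) data_error("negative survival time")
  if (!all(events %in% c(0, 1))) data_error("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
              surv = fit$surv, n = length(times))
  if (!is.null(horizon_months))
    out$surv_at_horizon <- km_survival_at(out, horizon_months)
  structure(out, class = "km_curve")
}

#' Survival probability of a KM curve at a time point
#'
#' @param km a `km_curve`.
#' @param t time in months.
#' @return `S(t)` as a step function evaluated at `t` (1 before the first
#'   event; the last value is carried beyond the observed range).
#' @export
km_survival_at <- function(km, t) {
  idx <- which(km$time <= t & km$n_event > 0)
  if (!length(idx)) return(1)
  km$surv[max(idx)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event times, S(last) = %.3f\n",
              x$n, sum(x$n_event > 0), min(x$surv)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ..., xlab = "Months", ylab = "Survival") {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[-(2 * length(x$surv))])
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over k groups
#' (`df = k - 1`), via `survival::survdiff`.
#'
#' @param groups list of groups, each a list with `times` and `events`.
#' @return List with `chi2`, `df`, `p`, and per-group `observed`/`expected`.
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2L) parameter_error("need at least two groups")
  times <- unlist(lapply(groups, `[[`, "times"))
  events <- unlist(lapply(groups, `[[`, "events"))
  g <- rep(seq_along(groups), vapply(groups, function(x) length(x$times),
                                     integer(1)))
  if (sum(events) < 1) parameter_error("no events in any group")
  if (any(times < 0)) data_error("negative survival time")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(groups) - 1L
  list(chi2 = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

endpoint_columns <- function(endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "OS") c(time = "os_months", event = "os_event")
  else c(time = "pfs_months", event = "pfs_event")
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Cox regression (Efron tie handling, labeled in the
#' result) on a patient-record data frame, reporting per-term hazard ratios
#' with Wald 95% confidence intervals. Suspiciously large coefficients are
#' flagged as possible separation rather than silently reported.
#'
#' @param records data frame with `os_months`/`os_event` (and
#'   `pfs_months`/`pfs_event` for PFS) plus the covariate columns.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param covariates character vector of covariate column names.
#' @param ties tie-handling method (only `"efron"` is offered).
#' @return An object of class `cox_result`: `table` (term, HR, ci_low,
#'   ci_high, p), `loglik`, `n`, `n_events`, `covariates`, `ties`,
#'   `warnings`, `selection_trace` (NULL unless produced by
#'   [screen_and_select()]), and the underlying `fit`.
#' @export
cox_fit <- function(records, endpoint = "OS", covariates, ties = "efron") {
  ties <- match.arg(ties, "efron")
  cols <- endpoint_columns(endpoint)
  missing_cols <- setdiff(c(cols, covariates), names(records))
  if (length(missing_cols))
    data_error(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  ev <- records[[cols["event"]]]
  if (sum(ev) < 1) fit_error("no events: Cox partial likelihood is undefined")
  for (v in covariates)
    if (length(unique(records[[v]])) < 2L)
      fit_error(paste("constant covariate:", v))
  fml <- stats::as.formula(paste0(
    "survival::Surv(", cols["time"], ", ", cols["event"], ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = records, ties = ties),
    error = function(e) fit_error(paste("Cox fit failed:", conditionMessage(e))))
  if (!is.null(fit$info) || any(is.na(stats::coef(fit))))
    fit_error("Cox fit did not converge")
  s <- summary(fit)
  co <- s$coefficients
  warnings <- character()
  if (any(abs(co[, "coef"]) > 15))
    warnings <- c(warnings, "possible separation: |log HR| > 15")
  tab <- data.frame(term = rownames(co), hr = co[, "exp(coef)"],
                    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"], row.names = NULL)
  structure(list(table = tab, loglik = fit$loglik, n = s$n,
                 n_events = s$nevent, covariates = covariates, ties = ties,
                 endpoint = endpoint, warnings = warnings,
                 selection_trace = NULL, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %s, n = %d (%d events), ties = %s\n",
              x$endpoint, x$n, x$n_events, x$ties))
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$ci_low, tab$ci_high)
  print(tab[, c("term", "hr", "p")], row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  if (!is.null(x$selection_trace)) {
    cat("selection trace:\n")
    print(x$selection_trace, row.names = FALSE)
  }
  invisible(x)
}

# Likelihood-ratio p for a whole covariate (handles multi-level factors as
# one term), by refitting without it.
covariate_lrt_p <- function(records, endpoint, covariates, drop) {
  full <- cox_fit(records, endpoint, covariates)
  kept <- setdiff(covariates, drop)
  if (length(kept)) {
    red <- cox_fit(records, endpoint, kept)
    ll0 <- red$loglik[2]
    df <- length(stats::coef(full$fit)) - length(stats::coef(red$fit))
  } else {
    ll0 <- full$loglik[1]
    df <- length(stats::coef(full$fit))
  }
  stats::pchisq(max(2 * (full$loglik[2] - ll0), 0), max(df, 1L),
                lower.tail = FALSE)
}

#' Univariable screen and backward selection around a forced exposure
#'
#' Reproduces the conventional model-building recipe: each candidate
#' covariate is screened univariably (likelihood-ratio test); those with
#' p < `p_enter` (default 0.10) enter the multivariable model together with
#' the exposure; backward elimination then repeatedly drops the
#' highest-p candidate while that p is at or above `p_stay` (default 0.05).
#' The exposure is forced: it is never screened out and never eliminated.
#' The full selection trace is recorded on the returned fit.
#'
#' @inheritParams cox_fit
#' @param candidate_covariates covariates subject to screening/elimination.
#' @param exposure covariate of interest, always retained.
#' @param p_enter univariable entry threshold.
#' @param p_stay backward-elimination stay threshold.
#' @return A [cox_fit()] result for the final model, with `selection_trace`
#'   (data frame of step, action, covariate, p) filled in.
#' @export
screen_and_select <- function(records, endpoint = "OS", candidate_covariates,
                              exposure, p_enter = 0.10, p_stay = 0.05) {
  if (!length(candidate_covariates)) parameter_error("no candidate covariates")
  if (exposure %in% candidate_covariates)
    candidate_covariates <- setdiff(candidate_covariates, exposure)
  trace <- data.frame(step = integer(), action = character(),
                      covariate = character(), p = numeric())
  step <- 0L
  entered <- character()
  for (v in candidate_covariates) {
    p <- covariate_lrt_p(records, endpoint, v, v)
    step <- step + 1L
    act <- if (p < p_enter) "enter" else "screen_out"
    trace <- rbind(trace, data.frame(step = step, action = act,
                                     covariate = v, p = p))
    if (p < p_enter) entered <- c(entered, v)
  }
  current <- entered
  repeat {
    if (!length(current)) break
    ps <- vapply(current, function(v)
      covariate_lrt_p(records, endpoint, c(exposure, current), v), numeric(1))
    worst <- which.max(ps)
    if (ps[worst] < p_stay) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, action = "drop",
                                     covariate = current[worst],
                                     p = ps[worst]))
    current <- current[-worst]
  }
  out <- cox_fit(records, endpoint, c(exposure, current))
  out$selection_trace <- trace
  out$exposure <- exposure
  out
}

#' Association test with chi-square / Fisher dispatch
#'
#' Computes the expected cell counts of a contingency table; if more than
#' 20% of cells have expected count below 5, Fisher's exact test is used,
#' otherwise the Pearson chi-square test without continuity correction.
#'
#' @param table matrix of non-negative integer counts with positive margins.
#' @return List with `test_name` (`"chi_square"` or `"fisher_exact"`),
#'   `statistic` (`NA` for Fisher), `p`, and the `expected` counts.
#' @export
association_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    data_error("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    data_error("contingency table has a zero margin")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (mean(expected < 5) > 0.2) {
    ft <- stats::fisher.test(table)
    list(test_name = "fisher_exact", statistic = NA_real_, p = ft$p.value,
         expected = expected)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(test_name = "chi_square", statistic = unname(ct$statistic),
         p = ct$p.value, expected = expected)
  }
}

#' Ordinal TIL count bins
#'
#' Immunohistochemistry lymphocyte counts are binned as 0, 1-5, 6-19, 20-49,
#' 50-100, >100 positive cells (ordinal codes 0..5). `til_bin` converts raw
#' counts; the per-patient value is the maximum over cores.
#'
#' @param counts non-negative cell counts.
#' @return Integer bin codes 0..5.
#' @export
til_bin <- function(counts) {
  if (any(counts < 0)) data_error("negative cell count")
  findInterval(counts, c(1, 6, 20, 50, 101))
}

#' Categorize patients by TIL density
#'
#' Thresholds are computed on the empirical distribution of the ordinal bin
#' codes. `quartile_binary` labels the highest quartile HIGH (threshold =
#' ceiling of the 75th percentile; a tied mass containing the boundary goes
#' entirely to the upper side). `tertile_3way` uses the 25th and 75th
#' percentiles the same way to produce LOW / MEDIUM / HIGH. An all-equal
#' input is degenerate: everyone is LOW and the result carries a
#' `degenerate` flag.
#'
#' @param bins per-patient ordinal codes 0..5 (n >= 4).
#' @param scheme `"quartile_binary"` or `"tertile_3way"`.
#' @return Character vector of categories with attributes `thresholds` and
#'   `degenerate`.
#' @export
categorize_til <- function(bins, scheme = c("quartile_binary", "tertile_3way")) {
  scheme <- match.arg(scheme)
  if (!length(bins)) data_error("empty TIL input")
  if (length(bins) < 4L) data_error("need at least 4 patients")
  if (!all(bins %in% 0:5)) parameter_error("bins must be ordinal codes 0..5")
  if (length(unique(bins)) == 1L) {
    out <- rep("LOW", length(bins))
    attr(out, "thresholds") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  thr <- function(prob) ceiling(stats::quantile(bins, prob, type = 7, names = FALSE))
  if (scheme == "quartile_binary") {
    t75 <- thr(0.75)
    out <- ifelse(bins >= t75, "HIGH", "LOW")
    attr(out, "thresholds") <- c(high = t75)
  } else {
    t25 <- thr(0.25); t75 <- thr(0.75)
    out <- ifelse(bins >= t75, "HIGH", ifelse(bins >= t25, "MEDIUM", "LOW"))
    attr(out, "thresholds") <- c(low = t25, high = t75)
  }
  attr(out, "degenerate") <- FALSE
  out
}

#' Joint TSR x TIL risk group
#'
#' Three-tier prognostic class: LOW risk = stroma-poor with high TILs,
#' HIGH risk = stroma-rich with low TILs, MEDIUM risk = the two mixed
#' combinations.
#'
#' @param stroma_category `"STROMA_RICH"` / `"STROMA_POOR"` per patient.
#' @param til_binary `"HIGH"` / `"LOW"` per patient.
#' @return Character vector of `"LOW"`, `"MEDIUM"`, `"HIGH"` risk labels.
#' @export
joint_risk_group <- function(stroma_category, til_binary) {
  if (length(stroma_category) != length(til_binary))
    data_error("inputs must be aligned")
  if (any(is.na(stroma_category)) || any(is.na(til_binary)))
    data_error("missing stroma category or TIL group")
  if (!all(stroma_category %in% c("STROMA_RICH", "STROMA_POOR")))
    parameter_error("invalid stroma category")
  if (!all(til_binary %in% c("HIGH", "LOW")))
    parameter_error("invalid TIL group")
  rich <- stroma_category == "STROMA_RICH"
  low_til <- til_binary == "LOW"
  ifelse(rich & low_til, "HIGH", ifelse(!rich & !low_til, "LOW", "MEDIUM"))
}

#' Read / write the clinical cohort CSV
#'
#' One row per patient with the schema: `patient_id, treatment, os_months,
#' os_event, pfs_months, pfs_event, age_group, figo_stage, residual_status,
#' cd8_bin, cd20_bin, cd68_bin, cd103_bin, tsr_manual_mi, tsr_manual_wt,
#' tsr_auto_mi, tsr_auto_wt`. Missing values are empty fields. `read_cohort`
#' validates and reports offending row numbers.
#'
#' @param path CSV path.
#' @return A data frame of patient records.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param records data frame conforming to the schema.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

COHORT_COLUMNS <- c("patient_id", "treatment", "os_months", "os_event",
                    "pfs_months", "pfs_event", "age_group", "figo_stage",
                    "residual_status", "cd8_bin", "cd20_bin", "cd68_bin",
                    "cd103_bin", "tsr_manual_mi", "tsr_manual_wt",
                    "tsr_auto_mi", "tsr_auto_wt")

validate_cohort <- function(df) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    data_error(paste("cohort is missing columns:",
                     paste(missing_cols, collapse = ", ")))
  problems <- character()
  bad_row <- function(ok, what) {
    if (any(!ok, na.rm = TRUE))
      problems <<- c(problems, sprintf("%s (rows %s)", what,
        paste(utils::head(which(!ok), 10), collapse = ", ")))
  }
  bad_row(df$os_months >= 0, "negative os_months")
  bad_row(df$pfs_months >= 0, "negative pfs_months")
  bad_row(df$os_event %in% c(0, 1), "os_event not 0/1")
  bad_row(df$pfs_event %in% c(0, 1), "pfs_event not 0/1")
  bad_row(is.na(df$pfs_months) | df$pfs_months <= df$os_months + 1e-9,
          "pfs_months exceeds os_months")
  bad_row(df$treatment %in% c("PDS", "NACT"), "treatment not PDS/NACT")
  if (length(problems))
    data_error(paste("cohort schema violations:",
                     paste(problems, collapse = "; ")))
  df
}
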