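#' Measure the tumor-stroma ratio inside a region of measurement
#'
#' TSR is the stromal percentage among tumor+stroma pixels inside the region:
#' `100 * n_stroma / (n_stroma + n_tumor)`. Background pixels inside the
#' region are counted but excluded from the ratio; NODATA is ignored
#' entirely. The stroma-rich/stroma-poor category applies the cutoff rule of
#' [stratify()].
#'
#' @param cm a [class_map()].
#' @param rom a [region_of_measurement()] aligned to `cm`.
#' @param cutoff_percent stroma-rich cutoff (default 50).
#' @return An object of class `tsr_result`: `stroma_percent`, `n_tumor_px`,
#'   `n_stroma_px`, `n_background_px_excluded`, `rom_kind`, `category`,
#'   `cutoff_percent`.
#' @examples
#' m <- matrix(2L, 10, 10); m[1:3, ] <- 1L
#' cm <- class_map(m, slide_meta("ex", 8, 10, 10))
#' rom <- region_of_measurement(matrix(TRUE, 10, 10), "WT")
#' measure_tsr(cm, rom)$stroma_percent  # 70
#' @export
measure_tsr <- function(cm, rom, cutoff_percent = 50) {
  if (!identical(dim(rom$mask), dim(cm$labels)))
    size_error("region mask is not aligned to the class map")
  sel <- cm$labels[rom$mask]
  n_t <- sum(sel == CLASS_CODES[["TUMOR"]])
  n_s <- sum(sel == CLASS_CODES[["STROMA"]])
  n_b <- sum(sel == CLASS_CODES[["BACKGROUND"]])
  if (n_t + n_s == 0L)
    empty_tissue_error("region contains no tumor or stroma pixels")
  pct <- 100 * n_s / (n_s + n_t)
  structure(list(stroma_percent = pct, n_tumor_px = n_t, n_stroma_px = n_s,
                 n_background_px_excluded = n_b, rom_kind = rom$kind,
                 category = stratify(pct, cutoff_percent),
                 cutoff_percent = cutoff_percent),
            class = "tsr_result")
}

#' @export
print.tsr_result <- function(x, ...) {
  cat(sprintf("<tsr_result> %s: %.2f%% stroma (%d stroma / %d tumor px, %d background excluded) -> %s\n",
              x$rom_kind, x$stroma_percent, x$n_stroma_px, x$n_tumor_px,
              x$n_background_px_excluded, x$category))
  invisible(x)
}

#' Stratify a stromal percentage into stroma-rich / stroma-poor
#'
#' Stroma-rich means stromal percentage at or above the cutoff (default 50,
#' inclusive); below is stroma-poor.
#'
#' @param stroma_percent stromal percentage(s) in `[0, 100]`.
#' @param cutoff_percent cutoff; the comparison is `>=`.
#' @return Character vector of `"STROMA_RICH"` / `"STROMA_POOR"`.
#' @export
stratify <- function(stroma_percent, cutoff_percent = 50) {
  if (any(!is.finite(stroma_percent)) || any(stroma_percent < 0) ||
      any(stroma_percent > 100))
    parameter_error("stroma_percent must lie in [0, 100]")
  ifelse(stroma_percent >= cutoff_percent, "STROMA_RICH", "STROMA_POOR")
}

#' A manual tenfold TSR score
#'
#' Pathologists score the stromal percentage per tenfold (0, 10, ..., 100)
#' for a named region (MI or WT).
#'
#' @param rater_id opaque rater identifier.
#' @param stroma_percent_tenfold integer multiple of 10 in `[0, 100]`.
#' @param region `"MI"` or `"WT"`.
#' @return An object of class `manual_score`.
#' @export
manual_score <- function(rater_id, stroma_percent_tenfold,
                         region = c("MI", "WT")) {
  region <- match.arg(region)
  v <- stroma_percent_tenfold
  if (length(v) != 1L || !is.finite(v) || v %% 10 != 0 || v < 0 || v > 100)
    parameter_error("manual score must be a tenfold percentage in 0..100")
  structure(list(rater_id = rater_id, stroma_percent_tenfold = as.integer(v),
                 region = region), class = "manual_score")
}

#' Consensus of manual TSR scores
#'
#' Two concordant raters decide; on discordance a third rater is required
#' and the consensus is the median of the three (a deterministic stand-in
#' for a consensus discussion, flagged in the result's `method`).
#'
#' @param score_a,score_b [manual_score()]s of the two primary raters.
#' @param score_c optional [manual_score()] of the adjudicating rater.
#' @return List with `value` and `method` (`"agreement"` or
#'   `"median_of_three"`).
#' @export
consensus_manual <- function(score_a, score_b, score_c = NULL) {
  for (s in list(score_a, score_b))
    if (!inherits(s, "manual_score")) parameter_error("scores must be manual_score objects")
  if (score_a$region != score_b$region)
    parameter_error("scores refer to different regions")
  a <- score_a$stroma_percent_tenfold; b <- score_b$stroma_percent_tenfold
  if (a == b) return(list(value = a, method = "agreement"))
  if (is.null(score_c))
    consensus_required_error("discordant pair: a third rater's score is required")
  if (!inherits(score_c, "manual_score") || score_c$region != score_a$region)
    parameter_error("third score must be a manual_score for the same region")
  list(value = stats::median(c(a, b, score_c$stroma_percent_tenfold)),
       method = "median_of_three")
}

#' Concordance between two score series
#'
#' Pearson product-moment correlation plus the intraclass correlation
#' coefficient ICC(2,1) — two-way random effects, absolute agreement, single
#' rater — computed from the two-way ANOVA mean squares. Absolute-agreement
#' ICC penalizes systematic shifts between raters that Pearson ignores.
#'
#' @param scores_x,scores_y equal-length numeric vectors (n >= 3), each
#'   non-constant.
#' @return An object of class `concordance_result`: `pearson_r`, `icc`,
#'   `n_pairs`, `icc_model`.
#' @export
concordance <- function(scores_x, scores_y) {
  if (length(scores_x) != length(scores_y))
    parameter_error("score series must have equal length")
  ok <- is.finite(scores_x) & is.finite(scores_y)
  x <- scores_x[ok]; y <- scores_y[ok]
  if (length(x) < 3L) parameter_error("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    degenerate_input_error("a score series is constant")
  structure(list(pearson_r = stats::cor(x, y), icc = icc21(cbind(x, y)),
                 n_pairs = length(x),
                 icc_model = "ICC(2,1) two-way random, absolute agreement, single rater"),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> n = %d: Pearson r = %.3f, ICC = %.3f [%s]\n",
              x$n_pairs, x$pearson_r, x$icc, x$icc_model))
  invisible(x)
}

# ICC(2,1) from the two-way random-effects ANOVA decomposition of an
# n-subjects x k-raters matrix:
#   (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)
icc21 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  rm_ <- rowMeans(mat); cm_ <- colMeans(mat)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm_ - gm)^2) / (k - 1)
  mse <- sum((mat - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + gm)^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Survival-optimal TSR cutoff search
#'
#' Scans a grid of candidate cutoffs, dichotomizes patients at each
#' (stroma-rich means TSR >= cutoff), computes the two-group log-rank
#' chi-square, and returns the cutoff with the highest discriminative power
#' for overall survival. Cutoffs that leave fewer than `min_group_size`
#' patients on either side are recorded as skipped (log-rank degeneracy
#' guard). No multiple-testing correction is applied — the full grid is
#' returned so callers can apply one.
#'
#' @param tsr_percent per-patient TSR percentages.
#' @param os_time,os_event survival times (months) and event indicators (0/1).
#' @param grid_step cutoff grid spacing in percentage points.
#' @param grid_range two-element range of cutoffs to scan.
#' @param min_group_size minimum patients per side for a cutoff to be
#'   admissible.
#' @return An object of class `cutoff_search_result`: `grid` (data frame of
#'   cutoff, chi2, p, skipped), `optimal_cutoff_percent`, `n`.
#' @export
optimal_cutoff_search <- function(tsr_percent, os_time, os_event,
                                  grid_step = 1, grid_range = c(5, 95),
                                  min_group_size = 5) {
  n <- length(tsr_percent)
  if (length(os_time) != n || length(os_event) != n)
    parameter_error("tsr_percent, os_time, os_event must be aligned")
  if (any(os_time < 0)) data_error("negative survival time")
  if (sum(os_event) < 1) data_error("at least one event is required")
  cutoffs <- seq(grid_range[1], grid_range[2], by = grid_step)
  chi2 <- p <- rep(NA_real_, length(cutoffs))
  skipped <- logical(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    g <- tsr_percent >= cutoffs[i]
    if (sum(g) < min_group_size || sum(!g) < min_group_size) {
      skipped[i] <- TRUE
      next
    }
    lr <- logrank_test(list(list(times = os_time[g], events = os_event[g]),
                            list(times = os_time[!g], events = os_event[!g])))
    chi2[i] <- lr$chi2; p[i] <- lr$p
  }
  if (all(skipped)) no_admissible_cutoff_error(
    "no cutoff leaves enough patients on both sides")
  best <- which(!skipped)[which.max(chi2[!skipped])]
  structure(list(
    grid = data.frame(cutoff_percent = cutoffs, logrank_chi2 = chi2, p = p,
                      skipped = skipped),
    optimal_cutoff_percent = cutoffs[best], n = n),
    class = "cutoff_search_result")
}

#' @export
print.cutoff_search_result <- function(x, ...) {
  i <- match(x$optimal_cutoff_percent, x$grid$cutoff_percent)
  cat(sprintf("<cutoff_search> optimal cutoff %.1f%% (chi2 = %.2f, p = %.3g) over %d admissible cutoffs, n = %d\n",
              x$optimal_cutoff_percent, x$grid$logrank_chi2[i], x$grid$p[i],
              sum(!x$grid$skipped), x$n))
  invisible(x)
}
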