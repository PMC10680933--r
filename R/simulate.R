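# Synthetic-data module: label rasters with known stromal fractions and
# cohorts with known hazard structure. Generators are pure functions of
# (spec, seed): the caller's RNG state is saved and restored.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic tissue class map
#'
#' Describes the stated world a generated mask emulates: raster geometry, a
#' planted most-invasive disk with a target stroma fraction (hit exactly up
#' to pixel rounding by quantile-thresholding a smooth noise field), a target
#' stroma fraction for the tissue outside the disk, background blobs standing
#' in for necrosis/adipose, and tumor nests of interdigitated tissue.
#'
#' @param width_px,height_px raster size in pixels.
#' @param mpp micrometers per pixel.
#' @param target_stroma_fraction_mi stroma/(stroma+tumor) target inside the
#'   planted 1.6 mm disk.
#' @param target_stroma_fraction_wt same target for tissue outside the disk.
#' @param background_blob_fraction fraction of the map carved into
#'   background blobs before tissue is painted.
#' @param n_tumor_nests number of additional tissue blobs outside the disk.
#' @param seed RNG seed; fully determines the output.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(width_px = 640L, height_px = 640L, mpp = 8,
                      target_stroma_fraction_mi = 0.5,
                      target_stroma_fraction_wt = 0.5,
                      background_blob_fraction = 0.08,
                      n_tumor_nests = 3L, seed = 1L) {
  fr <- c(target_stroma_fraction_mi, target_stroma_fraction_wt,
          background_blob_fraction)
  if (any(fr < 0) || any(fr > 1)) spec_error("fractions must lie in [0, 1]")
  if (mpp <= 0) spec_error("mpp must be positive")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), mpp = mpp,
                 target_stroma_fraction_mi = target_stroma_fraction_mi,
                 target_stroma_fraction_wt = target_stroma_fraction_wt,
                 background_blob_fraction = background_blob_fraction,
                 n_tumor_nests = as.integer(n_tumor_nests),
                 seed = as.integer(seed)),
            class = "mask_spec")
}

# Smooth noise field: standard normal pixels averaged over a disk kernel.
smooth_noise <- function(H, W, radius_px = 6) {
  z <- matrix(stats::rnorm(H * W), H, W)
  disk_sum(z, radius_px) / disk_sum(matrix(1, H, W), radius_px)
}

#' Generate a synthetic class map with known ground truth
#'
#' Paints a tissue region (a planted 1.6 mm disk plus random nests), carves
#' background blobs from thresholded smooth noise, and assigns tumor versus
#' stroma inside each region by thresholding an independent smooth noise
#' field at the empirical quantile of the target fraction — so the realized
#' stroma fraction matches the target up to a single pixel. The ground-truth
#' record reports realized fractions by exact pixel count.
#'
#' @param spec a [mask_spec()].
#' @return List with `classmap` (a [class_map()]) and `truth`: planted disk
#'   center/radius, exact per-region pixel tallies and stroma fractions, and
#'   the spec.
#' @export
generate_mask <- function(spec) {
  stopifnot(inherits(spec, "mask_spec"))
  H <- spec$height_px; W <- spec$width_px
  radius_px <- 1600 / spec$mpp
  if (2 * radius_px + 1 > min(H, W))
    spec_error("planted 1.6 mm disk does not fit inside the map")
  with_seed(spec$seed, {
    margin <- ceiling(radius_px) + 1
    center <- c(row = sample(margin:(H - margin), 1),
                col = sample(margin:(W - margin), 1))
    disk <- disk_mask(H, W, center[1], center[2], radius_px)

    tissue <- disk
    for (i in seq_len(spec$n_tumor_nests)) {
      r <- stats::runif(1, 0.25, 0.6) * radius_px
      cr <- sample(seq_len(H), 1); cc <- sample(seq_len(W), 1)
      tissue <- tissue | disk_mask(H, W, cr, cc, r)
    }
    # background blobs carved everywhere (necrosis/adipose stand-ins)
    if (spec$background_blob_fraction > 0) {
      nb <- smooth_noise(H, W, radius_px = max(3, radius_px / 20))
      blob <- nb > stats::quantile(nb, 1 - spec$background_blob_fraction)
      tissue <- tissue & !blob
    }

    labels <- matrix(CLASS_CODES[["BACKGROUND"]], H, W)
    zn <- smooth_noise(H, W, radius_px = max(3, radius_px / 12))
    paint_region <- function(region, target) {
      idx <- which(region)
      if (!length(idx)) return(invisible())
      n_stroma <- round(target * length(idx))
      ord <- idx[order(zn[idx])]
      labels[ord[seq_len(n_stroma)]] <<- CLASS_CODES[["STROMA"]]
      if (n_stroma < length(idx))
        labels[ord[(n_stroma + 1):length(idx)]] <<- CLASS_CODES[["TUMOR"]]
      invisible()
    }
    paint_region(tissue & disk, spec$target_stroma_fraction_mi)
    paint_region(tissue & !disk, spec$target_stroma_fraction_wt)

    cm <- class_map(labels, slide_meta(
      sprintf("synthetic-%d", spec$seed), spec$mpp, W, H))

    count_in <- function(region, code) sum(labels[region] == code)
    s_mi <- count_in(disk, CLASS_CODES[["STROMA"]])
    t_mi <- count_in(disk, CLASS_CODES[["TUMOR"]])
    s_wt <- count_in(!disk, CLASS_CODES[["STROMA"]])
    t_wt <- count_in(!disk, CLASS_CODES[["TUMOR"]])
    truth <- list(
      mi_center = center, mi_radius_px = radius_px, mi_radius_um = 1600,
      n_stroma_mi = s_mi, n_tumor_mi = t_mi,
      n_background_mi = sum(disk) - s_mi - t_mi,
      stroma_fraction_mi = if (s_mi + t_mi > 0) s_mi / (s_mi + t_mi) else NA_real_,
      n_stroma_outside = s_wt, n_tumor_outside = t_wt,
      stroma_fraction_outside = if (s_wt + t_wt > 0) s_wt / (s_wt + t_wt) else NA_real_,
      spec = spec)
    list(classmap = cm, truth = truth)
  })
}

#' Specification of a synthetic patient cohort
#'
#' Proportional-hazards world with an exponential baseline calibrated to a
#' median overall survival, multiplicative hazards for stroma-rich tumors and
#' low TIL density, independent uniform right-censoring calibrated to a
#' target censoring fraction, and progression generated as a Beta-distributed
#' fraction of the latent death time (so PFS <= OS by construction).
#'
#' Defaults state the world of an advanced-stage HGSOC cohort: n = 340,
#' median OS 38.3 months, 14% censoring, stroma-rich prevalence 0.33, PDS
#' arm fraction 0.415, crude-scale hazard ratios 1.6 (stroma-rich) and 1.5
#' (low TIL).
#'
#' @param n_patients cohort size.
#' @param hr_stroma_rich hazard ratio of stroma-rich vs stroma-poor.
#' @param hr_til_low hazard ratio of low-TIL vs high-TIL patients.
#' @param baseline_median_os_months median OS of the reference group.
#' @param censoring_fraction target fraction censored, in `[0, 1)`.
#' @param prevalence_stroma_rich probability a patient is stroma-rich.
#' @param til_bin_distribution probabilities over ordinal TIL codes 0..5.
#' @param pds_fraction probability of the PDS treatment arm.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 340L, hr_stroma_rich = 1.6,
                        hr_til_low = 1.5, baseline_median_os_months = 38.3,
                        censoring_fraction = 0.14,
                        prevalence_stroma_rich = 0.33,
                        til_bin_distribution = c(0.10, 0.15, 0.20, 0.25,
                                                 0.15, 0.15),
                        pds_fraction = 0.415, seed = 1L) {
  if (hr_stroma_rich <= 0 || hr_til_low <= 0)
    spec_error("hazard ratios must be positive")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    spec_error("censoring_fraction must lie in [0, 1)")
  if (prevalence_stroma_rich < 0 || prevalence_stroma_rich > 1)
    spec_error("prevalence must lie in [0, 1]")
  if (length(til_bin_distribution) != 6L ||
      abs(sum(til_bin_distribution) - 1) > 1e-8 ||
      any(til_bin_distribution < 0))
    spec_error("til_bin_distribution must be 6 probabilities summing to 1")
  structure(list(n_patients = as.integer(n_patients),
                 hr_stroma_rich = hr_stroma_rich, hr_til_low = hr_til_low,
                 baseline_median_os_months = baseline_median_os_months,
                 censoring_fraction = censoring_fraction,
                 prevalence_stroma_rich = prevalence_stroma_rich,
                 til_bin_distribution = til_bin_distribution,
                 pds_fraction = pds_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Uniform(0, b) censoring bound achieving the target mean censoring fraction
# for an exponential mixture with rates `rates`: P(censored | rate) =
# (1 - exp(-rate b)) / (rate b), solved for b by uniroot.
censoring_bound <- function(rates, target) {
  f <- function(logb) {
    b <- exp(logb)
    mean((1 - exp(-rates * b)) / (rates * b)) - target
  }
  sol <- tryCatch(stats::uniroot(f, c(log(1e-4), log(1e6))),
                  error = function(e) spec_error(
                    "infeasible censoring target for this hazard structure"))
  exp(sol$root)
}

#' Generate a synthetic patient cohort with known hazard structure
#'
#' Draws stroma-rich status and a causal TIL marker (CD8), assigns each
#' patient the hazard `log(2)/median * hr_stroma_rich^[rich] *
#' hr_til_low^[low TIL]`, and simulates exponential death times with uniform
#' censoring calibrated to the requested censoring fraction. TSR covariates
#' consistent with the stroma category (continuous automated scores and
#' tenfold manual scores) and non-causal covariates/markers complete the
#' cohort schema of [read_cohort()].
#'
#' @param spec a [cohort_spec()].
#' @return List with `records` (data frame in the cohort CSV schema plus the
#'   latent `stroma_rich`/`til_high` columns) and `true_params` (every
#'   generative constant, including the TIL high threshold and censoring
#'   bound).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    rich <- stats::runif(n) < spec$prevalence_stroma_rich
    cd8 <- sample(0:5, n, replace = TRUE, prob = spec$til_bin_distribution)
    # theoretical top-quartile threshold with the tied-mass-up rule
    cdf <- cumsum(spec$til_bin_distribution)
    # smallest code t with P(bin >= t) <= 0.25; cdf[i] = P(bin <= i - 1)
    til_threshold <- min(which(1 - cdf <= 0.25 + 1e-12))
    til_high <- cd8 >= til_threshold
    base_rate <- log(2) / spec$baseline_median_os_months
    rates <- base_rate * spec$hr_stroma_rich^rich * spec$hr_til_low^(!til_high)
    death <- stats::rexp(n, rates)
    if (spec$censoring_fraction > 0) {
      b <- censoring_bound(rates, spec$censoring_fraction)
      cens <- stats::runif(n, 0, b)
    } else {
      b <- Inf
      cens <- rep(Inf, n)
    }
    os <- pmin(death, cens)
    os_event <- as.integer(death <= cens)
    prog <- death * stats::rbeta(n, 2, 3)
    pfs <- pmin(prog, cens)
    pfs_event <- as.integer(prog <= cens)

    tsr_mi <- ifelse(rich, stats::runif(n, 50, 95), stats::runif(n, 2, 49.9))
    tsr_wt <- pmin(99, pmax(1, tsr_mi + stats::rnorm(n, 0, 6)))
    tenfold <- function(x) pmin(100, pmax(0, round((x + stats::rnorm(n, 0, 5)) / 10) * 10))
    records <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      treatment = ifelse(stats::runif(n) < spec$pds_fraction, "PDS", "NACT"),
      os_months = os, os_event = os_event,
      pfs_months = pfs, pfs_event = pfs_event,
      age_group = sample(c("<65", "65-75", ">75"), n, replace = TRUE,
                         prob = c(0.45, 0.38, 0.17)),
      figo_stage = sample(c("II", "III", "IV"), n, replace = TRUE,
                          prob = c(0.06, 0.64, 0.30)),
      residual_status = sample(c("suboptimal", "optimal", "complete"), n,
                               replace = TRUE, prob = c(0.09, 0.33, 0.58)),
      cd8_bin = cd8,
      cd20_bin = sample(0:5, n, replace = TRUE, prob = spec$til_bin_distribution),
      cd68_bin = sample(0:5, n, replace = TRUE, prob = spec$til_bin_distribution),
      cd103_bin = sample(0:5, n, replace = TRUE, prob = spec$til_bin_distribution),
      tsr_manual_mi = tenfold(tsr_mi), tsr_manual_wt = tenfold(tsr_wt),
      tsr_auto_mi = tsr_mi, tsr_auto_wt = tsr_wt,
      stroma_rich = rich, til_high = til_high,
      stringsAsFactors = FALSE)
    true_params <- list(base_rate = base_rate,
                        hr_stroma_rich = spec$hr_stroma_rich,
                        hr_til_low = spec$hr_til_low,
                        til_high_threshold = til_threshold,
                        censoring_bound = b, spec = spec)
    list(records = records, true_params = true_params)
  })
}
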