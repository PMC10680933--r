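#' Pipeline configuration
#'
#' Every tunable of the slide pipeline in one record. The serialized config
#' is hashed ([params_hash()]) and embedded in all outputs so any result is
#' attributable to the exact parameters that produced it.
#'
#' @param working_mpp resolution (micrometers/pixel) at which region
#'   geometry is computed; finer input maps are majority-vote downsampled.
#' @param patch_size_px,stride_px patch grid used when segmenting RGB input
#'   (50% overlap by default).
#' @param mi_radius_um most-invasive field-of-view radius.
#' @param mi_stride_px center-grid stride for the MI search (`NULL` =
#'   radius/16).
#' @param min_tissue_fraction validity threshold for MI candidates (strict).
#' @param wt_kernel_radius_um local-density kernel radius for the tumor bed.
#' @param tau_base,tau_max,area_ref_mm2 dynamic-threshold parameters.
#' @param min_component_mm2 minimum tumor-bed component area.
#' @param tsr_cutoff_percent stroma-rich cutoff.
#' @param seed seed recorded with outputs (the slide pipeline itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(working_mpp = 8, patch_size_px = 256L,
                            stride_px = 128L, mi_radius_um = 1600,
                            mi_stride_px = NULL,
                            min_tissue_fraction = 2 / 3,
                            wt_kernel_radius_um = 500, tau_base = 0.15,
                            tau_max = 0.50, area_ref_mm2 = 50,
                            min_component_mm2 = 0.1,
                            tsr_cutoff_percent = 50, seed = 1L) {
  structure(list(working_mpp = working_mpp, patch_size_px = patch_size_px,
                 stride_px = stride_px, mi_radius_um = mi_radius_um,
                 mi_stride_px = mi_stride_px,
                 min_tissue_fraction = min_tissue_fraction,
                 wt_kernel_radius_um = wt_kernel_radius_um,
                 tau_base = tau_base, tau_max = tau_max,
                 area_ref_mm2 = area_ref_mm2,
                 min_component_mm2 = min_component_mm2,
                 tsr_cutoff_percent = tsr_cutoff_percent,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialization, truncated to 12 hex digits.
#' Identical configs hash identically across runs and platforms.
#'
#' @param config a [pipeline_config()].
#' @return Character hash.
#' @export
params_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

#' Run the TSR pipeline on one slide
#'
#' Executes segmentation (only for RGB input), most-invasive and whole-tumor
#' region estimation, and TSR measurement in both regions. Input may be a
#' [class_map()], the path of a serialized class map (`.pgm` + JSON sidecar),
#' or the path of an RGB fixture (`.ppm`), which is segmented with the
#' reference palette classifier. Maps finer than `config$working_mpp` are
#' majority-vote downsampled before region geometry. A failing stage does
#' not abort the slide: it is recorded as a skip with its stage and reason,
#' mirroring how unscorable slides are excluded rather than crashing a batch.
#'
#' @param input class map, `.pgm` path, or `.ppm` path.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes `tsr.csv`, the ROM
#'   masks, and a run log.
#' @return An object of class `slide_report`: `report` (one CSV-schema row
#'   per measured region), `skips` (stage/reason records), `roms`, `config`,
#'   `params_hash`.
#' @export
run_slide <- function(input, config = pipeline_config(), out_dir = NULL) {
  cm <- if (inherits(input, "class_map")) {
    input
  } else if (grepl("\\.pgm$", input)) {
    read_classmap(input)
  } else if (grepl("\\.ppm$", input)) {
    rgb <- read_ppm(input)
    meta <- slide_meta(sub("\\.ppm$", "", basename(input)),
                       config$working_mpp, dim(rgb)[2], dim(rgb)[1])
    grid <- extract_patches(rgb, meta, config$patch_size_px, config$stride_px)
    stitch_to_classmap(classify_patches(grid, palette_classifier))
  } else {
    data_error(paste("unrecognized input:", input))
  }
  if (cm$meta$mpp < config$working_mpp) {
    k <- as.integer(round(config$working_mpp / cm$meta$mpp))
    if (k > 1L) cm <- downsample_classmap(cm, k)
  }
  hash <- params_hash(config)
  skips <- data.frame(stage = character(), reason = character())
  roms <- list()
  rows <- list()
  measure_in <- function(stage, rom_fn) {
    rom <- tryCatch(rom_fn(), tsrq_error = function(e) e)
    if (inherits(rom, "tsrq_error")) {
      skips <<- rbind(skips, data.frame(stage = stage,
                                        reason = conditionMessage(rom)))
      return(invisible())
    }
    res <- tryCatch(measure_tsr(cm, rom, config$tsr_cutoff_percent),
                    tsrq_error = function(e) e)
    if (inherits(res, "tsrq_error")) {
      skips <<- rbind(skips, data.frame(stage = paste0(stage, "/tsr"),
                                        reason = conditionMessage(res)))
      return(invisible())
    }
    roms[[stage]] <<- rom
    rows[[stage]] <<- data.frame(
      slide_id = cm$meta$slide_id, rom_kind = rom$kind,
      stroma_percent = res$stroma_percent, n_tumor_px = res$n_tumor_px,
      n_stroma_px = res$n_stroma_px, category = res$category,
      params_hash = hash, stringsAsFactors = FALSE)
    invisible()
  }
  measure_in("MI", function()
    find_most_invasive_fov(cm, config$mi_radius_um, config$mi_stride_px,
                           config$min_tissue_fraction)$rom)
  measure_in("WT", function()
    estimate_tumor_bed(cm, config$wt_kernel_radius_um, config$tau_base,
                       config$tau_max, config$area_ref_mm2,
                       config$min_component_mm2))
  report <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(slide_id = character(), rom_kind = character(),
               stroma_percent = numeric(), n_tumor_px = integer(),
               n_stroma_px = integer(), category = character(),
               params_hash = character())
  out <- structure(list(report = report, skips = skips, roms = roms,
                        classmap = cm, config = config, params_hash = hash),
                   class = "slide_report")
  if (!is.null(out_dir)) write_slide_report(out, out_dir)
  out
}

write_slide_report <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$report, file.path(out_dir, "tsr.csv"), row.names = FALSE)
  for (nm in names(x$roms))
    write_rom(x$roms[[nm]],
              file.path(out_dir, sprintf("rom_%s.pgm", tolower(nm))))
  log_lines <- c(
    sprintf("tsrquant %s", as.character(utils::packageVersion("tsrquant"))),
    sprintf("slide %s", x$classmap$meta$slide_id),
    sprintf("params_hash %s", x$params_hash),
    sprintf("skip %s: %s", x$skips$stage, x$skips$reason))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.slide_report <- function(x, ...) {
  cat(sprintf("<slide_report> %s (params %s)\n", x$classmap$meta$slide_id,
              x$params_hash))
  print(x$report, row.names = FALSE)
  if (nrow(x$skips))
    cat("skipped:", paste(x$skips$stage, x$skips$reason, sep = ": ",
                          collapse = "; "), "\n")
  invisible(x)
}

#' Run the cohort survival analysis
#'
#' Stratifies patients on a TSR column, then — for the combined cohort and
#' each treatment arm — produces Kaplan-Meier curves per stroma category with
#' the log-rank test, crude and adjusted Cox models (the TSR exposure forced
#' through a univariable screen and backward selection), the joint TSR x TIL
#' risk classifier with its own KM/log-rank, and stroma-category association
#' tables with the chi-square/Fisher dispatch label.
#'
#' @param cohort data frame or CSV path conforming to the [read_cohort()]
#'   schema.
#' @param config a [pipeline_config()] (supplies the TSR cutoff).
#' @param tsr_var TSR column used as exposure (default `"tsr_auto_mi"`).
#' @param til_var ordinal TIL column used for the joint classifier.
#' @param out_dir optional directory for CSV reports.
#' @return An object of class `cohort_report`: per-subgroup results
#'   (`combined`, `PDS`, `NACT`), plus `tsr_var`, `til_var`, `config`,
#'   `params_hash`.
#' @export
run_cohort <- function(cohort, config = pipeline_config(),
                       tsr_var = "tsr_auto_mi", til_var = "cd8_bin",
                       out_dir = NULL) {
  df <- if (is.character(cohort)) read_cohort(cohort) else validate_cohort(cohort)
  if (nrow(df) < 2L) data_error("cohort must contain at least 2 patients")
  if (!tsr_var %in% names(df)) data_error(paste("missing TSR column:", tsr_var))
  df <- df[is.finite(df[[tsr_var]]), , drop = FALSE]
  df$stroma_category <- stratify(df[[tsr_var]], config$tsr_cutoff_percent)
  df$til_group <- as.character(categorize_til(df[[til_var]], "quartile_binary"))
  df$risk_group <- joint_risk_group(df$stroma_category, df$til_group)

  analyse <- function(sub) {
    res <- list(n = nrow(sub))
    grab <- function(expr) tryCatch(expr, tsrq_error = function(e)
      list(error = conditionMessage(e)))
    res$km_by_category <- grab(lapply(
      split(sub, sub$stroma_category),
      function(g) km_estimate(g$os_months, g$os_event, horizon_months = 120)))
    res$logrank <- grab({
      gs <- split(sub, sub$stroma_category)
      if (length(gs) < 2L) parameter_error("only one stroma category present")
      logrank_test(lapply(gs, function(g)
        list(times = g$os_months, events = g$os_event)))
    })
    res$crude_cox <- grab(cox_fit(sub, "OS", "stroma_category"))
    candidates <- c("age_group", "figo_stage", "residual_status")
    if (length(unique(sub$treatment)) > 1L)
      candidates <- c(candidates, "treatment")
    res$adjusted_cox <- grab(screen_and_select(
      sub, "OS", candidates, exposure = "stroma_category"))
    res$joint_km <- grab(lapply(
      split(sub, sub$risk_group),
      function(g) km_estimate(g$os_months, g$os_event, horizon_months = 120)))
    res$joint_logrank <- grab({
      gs <- split(sub, sub$risk_group)
      if (length(gs) < 2L) parameter_error("only one risk group present")
      logrank_test(lapply(gs, function(g)
        list(times = g$os_months, events = g$os_event)))
    })
    res$association <- grab({
      tab <- table(sub$stroma_category, sub$til_group)
      if (any(dim(tab) < 2L)) data_error("degenerate association table")
      association_test(tab)
    })
    res
  }
  out <- list(combined = analyse(df),
              PDS = analyse(df[df$treatment == "PDS", , drop = FALSE]),
              NACT = analyse(df[df$treatment == "NACT", , drop = FALSE]),
              tsr_var = tsr_var, til_var = til_var, config = config,
              params_hash = params_hash(config), records = df)
  class(out) <- "cohort_report"
  if (!is.null(out_dir)) write_cohort_report(out, out_dir)
  out
}

write_cohort_report <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("combined", "PDS", "NACT")) {
    res <- x[[nm]]
    if (!is.null(res$crude_cox$table))
      utils::write.csv(res$crude_cox$table,
                       file.path(out_dir, sprintf("cox_crude_%s.csv", nm)),
                       row.names = FALSE)
    if (!is.null(res$adjusted_cox$table))
      utils::write.csv(res$adjusted_cox$table,
                       file.path(out_dir, sprintf("cox_adjusted_%s.csv", nm)),
                       row.names = FALSE)
    if (!is.null(res$km_by_category) && is.null(res$km_by_category$error)) {
      km_rows <- do.call(rbind, lapply(names(res$km_by_category), function(g) {
        km <- res$km_by_category[[g]]
        data.frame(group = g, time = km$time, n_risk = km$n_risk,
                   n_event = km$n_event, surv = km$surv)
      }))
      utils::write.csv(km_rows, file.path(out_dir, sprintf("km_%s.csv", nm)),
                       row.names = FALSE)
    }
  }
  writeLines(c(sprintf("params_hash %s", x$params_hash),
               sprintf("tsr_var %s", x$tsr_var),
               sprintf("til_var %s", x$til_var)),
             file.path(out_dir, "cohort_run.log"))
  invisible(out_dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> exposure %s at cutoff %g%%, n = %d\n",
              x$tsr_var, x$config$tsr_cutoff_percent, x$combined$n))
  for (nm in c("combined", "PDS", "NACT")) {
    res <- x[[nm]]
    lr <- res$logrank
    if (!is.null(lr$chi2))
      cat(sprintf("  %s (n = %d): log-rank chi2 = %.2f, p = %.3g\n",
                  nm, res$n, lr$chi2, lr$p))
    else cat(sprintf("  %s (n = %d): %s\n", nm, res$n,
                     lr$error %||% "no log-rank"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
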