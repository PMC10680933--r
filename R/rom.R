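#' Region of measurement
#'
#' A boolean raster aligned to a [class_map()] selecting the pixels inside
#' which TSR is tallied, together with its kind (`"MI"` for the most-invasive
#' field of view, `"WT"` for the whole-tumor bed) and the full parameter
#' record that produced it, so any region is replayable and auditable.
#'
#' @param mask logical matrix aligned to the class map.
#' @param kind `"MI"` or `"WT"`.
#' @param params named list of every parameter used.
#' @return An object of class `region_of_measurement`.
#' @export
region_of_measurement <- function(mask, kind = c("MI", "WT"), params = list()) {
  kind <- match.arg(kind)
  if (!is.logical(mask) || !is.matrix(mask))
    parameter_error("mask must be a logical matrix")
  structure(list(mask = mask, kind = kind, params = params),
            class = "region_of_measurement")
}

#' @export
print.region_of_measurement <- function(x, ...) {
  cat(sprintf("<region_of_measurement> kind %s, %d px selected of %d x %d\n",
              x$kind, sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

# Sum of `mat` over a pixel-centered disk of radius `radius_px` around every
# pixel, clipped at borders. Row prefix sums plus one vectorized pass per
# disk row keep this O((2R+1) * H * W) with no per-pixel R loop.
disk_sum <- function(mat, radius_px) {
  H <- nrow(mat); W <- ncol(mat)
  R <- as.integer(floor(radius_px))
  r2 <- radius_px^2
  P <- cbind(0, t(apply(mat, 1L, cumsum)))          # H x (W+1) row prefix sums
  out <- matrix(0, H, W)
  cols <- seq_len(W)
  for (dy in (-R):R) {
    w <- floor(sqrt(r2 - dy^2))
    hi <- pmin(cols + w, W) + 1L
    lo <- pmax(cols - w - 1L, 0L) + 1L
    rs <- max(1L, 1L - dy):min(H, H - dy)           # centers with row r+dy in bounds
    out[rs, ] <- out[rs, ] + (P[rs + dy, hi, drop = FALSE] -
                              P[rs + dy, lo, drop = FALSE])
  }
  out
}

# Logical disk mask (pixel-centered, radius in pixels, clipped at borders).
disk_mask <- function(H, W, center_row, center_col, radius_px) {
  dr <- (seq_len(H) - center_row)^2
  dc <- (seq_len(W) - center_col)^2
  outer(dr, dc, "+") <= radius_px^2
}

#' Find the most-invasive field of view
#'
#' Searches a regular grid of candidate centers for the circular 10x-objective
#' field of view (default radius 1.6 mm) with the highest tumor fraction,
#' where tumor fraction is tumor/(tumor+stroma) — background excluded from the
#' denominator. A candidate is only valid when more than `min_tissue_fraction`
#' (default 2/3, strict) of the disk's in-bounds area is tissue (tumor or
#' stroma); glass, necrosis and unscanned NODATA all count as non-tissue, so
#' fields hanging off the tissue border or the scanned region are rejected.
#' Ties break by higher tissue fraction, then row-major center order. Disks
#' clipped by the image border are normalized by their in-bounds area.
#'
#' @param cm a [class_map()].
#' @param radius_um field-of-view radius in micrometers.
#' @param stride_px spacing of the candidate-center grid in pixels; default
#'   `max(1, round(radius_px / 16))`.
#' @param min_tissue_fraction validity threshold on the disk tissue fraction.
#' @return A list with `fov` (the winning candidate: `center` 1-based
#'   `(row, col)`, `radius_um`, `tumor_fraction`, `tissue_fraction`) and
#'   `rom`, the [region_of_measurement()] (winning disk intersected with
#'   non-NODATA pixels).
#' @export
find_most_invasive_fov <- function(cm, radius_um = 1600,
                                   stride_px = NULL,
                                   min_tissue_fraction = 2 / 3) {
  lab <- cm$labels
  H <- nrow(lab); W <- ncol(lab)
  if (!any(lab != CLASS_CODES[["NODATA"]]))
    empty_map_error("class map contains no scanned pixels")
  radius_px <- radius_um / cm$meta$mpp
  if (is.null(stride_px)) stride_px <- max(1L, as.integer(round(radius_px / 16)))
  stride_px <- as.integer(stride_px)
  if (stride_px < 1L) parameter_error("stride_px must be >= 1")

  t_sum <- disk_sum(lab == CLASS_CODES[["TUMOR"]], radius_px)
  s_sum <- disk_sum(lab == CLASS_CODES[["STROMA"]], radius_px)
  n_sum <- disk_sum(matrix(1, H, W), radius_px)   # in-bounds disk area

  rows <- seq.int(1L, H, by = stride_px)
  colsg <- seq.int(1L, W, by = stride_px)
  # row-major candidate order: iterate rows outer, cols inner
  cr <- rep(rows, each = length(colsg))
  cc <- rep(colsg, times = length(rows))
  ij <- cbind(cr, cc)
  tis <- t_sum[ij] + s_sum[ij]
  nn <- n_sum[ij]
  tumor_fr <- ifelse(tis > 0, t_sum[ij] / tis, NA_real_)
  tissue_fr <- ifelse(nn > 0, tis / nn, 0)

  valid <- tissue_fr > min_tissue_fraction & tis > 0
  if (!any(valid)) {
    if (!any(tis > 0))
      empty_map_error("no candidate disk contains tumor or stroma")
    no_valid_fov_error(sprintf(
      "no candidate field of view exceeds tissue fraction %.3f",
      min_tissue_fraction))
  }
  cand <- which(valid)
  # argmax tumor fraction, ties -> higher tissue fraction -> row-major order
  best <- cand[order(-tumor_fr[cand], -tissue_fr[cand], cand)][1]
  center <- c(row = cr[best], col = cc[best])
  mask <- disk_mask(H, W, center[1], center[2], radius_px) &
    lab != CLASS_CODES[["NODATA"]]
  params <- list(radius_um = radius_um, radius_px = radius_px,
                 stride_px = stride_px,
                 min_tissue_fraction = min_tissue_fraction, mpp = cm$meta$mpp)
  list(
    fov = structure(list(center = center, radius_um = radius_um,
                         tumor_fraction = tumor_fr[best],
                         tissue_fraction = tissue_fr[best]),
                    class = "fov_candidate"),
    rom = region_of_measurement(mask, "MI", params)
  )
}

#' Local tumor density field
#'
#' For every pixel, the fraction of TUMOR pixels among the in-bounds
#' non-NODATA pixels of the disk of radius `kernel_radius_um` around it
#' (border disks are normalized by their in-bounds area; with
#' `tissue_only = TRUE` the denominator is restricted to tumor+stroma
#' pixels). NODATA pixels propagate as `NA`.
#'
#' @param cm a [class_map()].
#' @param kernel_radius_um disk radius in micrometers (must be at least one
#'   pixel, i.e. `>= cm$meta$mpp`).
#' @param tissue_only use tumor+stroma rather than all non-NODATA pixels as
#'   the denominator. The default keeps necrotic cores inside the tumor bed:
#'   background inside tumor lowers density smoothly instead of creating
#'   holes.
#' @return An object of class `density_field` with `values` (float raster in
#'   `[0, 1]`, `NA` at NODATA) and `kernel_radius_um`.
#' @export
local_tumor_density <- function(cm, kernel_radius_um, tissue_only = FALSE) {
  if (kernel_radius_um < cm$meta$mpp)
    parameter_error("kernel radius is smaller than one pixel")
  lab <- cm$labels
  radius_px <- kernel_radius_um / cm$meta$mpp
  num <- disk_sum(lab == CLASS_CODES[["TUMOR"]], radius_px)
  den <- if (tissue_only) {
    disk_sum(lab == CLASS_CODES[["TUMOR"]] | lab == CLASS_CODES[["STROMA"]],
             radius_px)
  } else {
    disk_sum(lab != CLASS_CODES[["NODATA"]], radius_px)
  }
  vals <- ifelse(den > 0, num / den, NA_real_)
  vals[lab == CLASS_CODES[["NODATA"]]] <- NA_real_
  structure(list(values = vals, kernel_radius_um = kernel_radius_um),
            class = "density_field")
}

#' Size-dependent tumor-bed density threshold
#'
#' The whole-tumor bed keeps pixels whose local tumor density exceeds a
#' threshold. For small tumors the threshold is raised linearly toward
#' `tau_max`, which shrinks the stroma margin retained around the tumor:
#' `tau(A) = tau_base` for `A >= area_ref_mm2`, else
#' `tau_base + (tau_max - tau_base) * (1 - A / area_ref_mm2)`. Monotonically
#' non-increasing in the tumor area `A`.
#'
#' @param tumor_area_mm2 total tumor area in mm^2.
#' @param tau_base threshold used for large tumors.
#' @param tau_max threshold approached as the tumor area goes to zero.
#' @param area_ref_mm2 area above which the base threshold applies.
#' @return The density threshold in `[tau_base, tau_max]`.
#' @export
dynamic_threshold <- function(tumor_area_mm2, tau_base = 0.15,
                              tau_max = 0.50, area_ref_mm2 = 50) {
  if (!(tau_base > 0 && tau_base <= tau_max && tau_max < 1))
    parameter_error("need 0 < tau_base <= tau_max < 1")
  if (area_ref_mm2 <= 0) parameter_error("area_ref_mm2 must be positive")
  if (tumor_area_mm2 < 0) parameter_error("tumor area must be non-negative")
  if (tumor_area_mm2 >= area_ref_mm2) return(tau_base)
  tau_base + (tau_max - tau_base) * (1 - tumor_area_mm2 / area_ref_mm2)
}

#' Estimate the whole-tumor bed
#'
#' Thresholds the local tumor density at the size-dependent value from
#' [dynamic_threshold()] (strictly greater-than), then removes connected
#' components smaller than `min_component_mm2` (4-neighbour connectivity).
#' The resulting mask covers the tumor plus a stroma margin whose width
#' shrinks as the threshold rises.
#'
#' @inheritParams local_tumor_density
#' @inheritParams dynamic_threshold
#' @param min_component_mm2 minimum area of a connected component to keep.
#' @return A [region_of_measurement()] of kind `"WT"`.
#' @export
estimate_tumor_bed <- function(cm, kernel_radius_um = 500, tau_base = 0.15,
                               tau_max = 0.50, area_ref_mm2 = 50,
                               min_component_mm2 = 0.1,
                               tissue_only = FALSE) {
  n_tumor <- sum(cm$labels == CLASS_CODES[["TUMOR"]])
  if (n_tumor == 0L) no_tumor_error("class map contains no tumor pixels")
  px_mm2 <- (cm$meta$mpp / 1000)^2
  tumor_area_mm2 <- n_tumor * px_mm2
  tau <- dynamic_threshold(tumor_area_mm2, tau_base, tau_max, area_ref_mm2)
  dens <- local_tumor_density(cm, kernel_radius_um, tissue_only = tissue_only)
  mask <- !is.na(dens$values) & dens$values > tau
  if (any(mask) && min_component_mm2 > 0) {
    comp <- label_components(mask)
    keep <- which(tabulate(comp[mask]) * px_mm2 >= min_component_mm2)
    mask <- mask & matrix(comp %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask))
    empty_rom_error(sprintf(
      "tumor-bed mask is empty at density threshold %.3f (tumor area %.3f mm^2)",
      tau, tumor_area_mm2))
  params <- list(kernel_radius_um = kernel_radius_um, tau_base = tau_base,
                 tau_max = tau_max, area_ref_mm2 = area_ref_mm2,
                 min_component_mm2 = min_component_mm2,
                 tissue_only = tissue_only, tau = tau,
                 tumor_area_mm2 = tumor_area_mm2, mpp = cm$meta$mpp)
  region_of_measurement(mask, "WT", params)
}

# 4-connected component labels over a logical mask; 0 outside the mask.
# igraph does the union-find; we only build the pixel adjacency edges.
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  idx <- which(mask)
  if (!length(idx)) return(out)
  id <- integer(H * W); id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  er <- idx[cc < W]; er <- er[mask[er + H]]      # right neighbours
  ed <- idx[r < H];  ed <- ed[mask[ed + 1L]]     # down neighbours
  edges <- c(rbind(id[c(er, ed)], id[c(er + H, ed + 1L)]))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  out[idx] <- as.integer(igraph::components(g)$membership)
  out
}

#' Serialize / load a region of measurement
#'
#' The mask is written as a 0/1 ASCII PGM; the parameter record (plus the
#' region kind) goes to the JSON sidecar, making every region replayable.
#'
#' @param rom a [region_of_measurement()].
#' @param path output `.pgm` path.
#' @export
write_rom <- function(rom, path) {
  write_pgm(matrix(as.integer(rom$mask), nrow(rom$mask)), path, maxval = 1L)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(list(kind = rom$kind, params = rom$params), sidecar,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rom
#' @export
read_rom <- function(path) {
  m <- read_pgm(path)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  region_of_measurement(m == 1L, js$kind, as.list(js$params))
}
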