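#' Extract overlapping patches from an RGB image
#'
#' Lays a regular grid of `patch_size_px` square tiles with spacing
#' `stride_px` over the image. The grid is clamped so the last row/column of
#' patches abuts the image border (no out-of-bounds reads), which guarantees
#' every pixel is covered by at least one patch. Coordinates are 0-based
#' (row, col) of each tile's top-left pixel.
#'
#' @param image RGB array `(H, W, 3)` with values 0..255.
#' @param meta a [slide_meta()] describing the image.
#' @param patch_size_px tile side length in pixels.
#' @param stride_px grid spacing in pixels (`<= patch_size_px` allows overlap).
#' @return An object of class `patch_grid`: `patch_size_px`, `stride_px`,
#'   `origins` (n x 2 integer matrix of 0-based row, col), and `patches`
#'   (list of RGB tiles aligned with `origins`).
#' @export
extract_patches <- function(image, meta, patch_size_px = 256L,
                            stride_px = 128L) {
  patch_size_px <- as.integer(patch_size_px)
  stride_px <- as.integer(stride_px)
  if (is.na(stride_px) || stride_px < 1L)
    parameter_error("stride_px must be a positive integer")
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H != meta$height_px || W != meta$width_px)
    size_error("image dimensions disagree with slide metadata")
  if (patch_size_px > min(H, W))
    size_error(sprintf("patch (%d px) larger than image (%d x %d)",
                       patch_size_px, H, W))
  origins_1d <- function(extent) {
    starts <- seq.int(0L, extent - patch_size_px, by = stride_px)
    if (starts[length(starts)] + patch_size_px < extent)
      starts <- c(starts, extent - patch_size_px)  # clamp final tile to border
    starts
  }
  rr <- origins_1d(H); cc <- origins_1d(W)
  origins <- cbind(row = rep(rr, times = length(cc)),
                   col = rep(cc, each = length(rr)))
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    r <- origins[i, 1]; c0 <- origins[i, 2]
    image[(r + 1L):(r + patch_size_px), (c0 + 1L):(c0 + patch_size_px), ,
          drop = FALSE]
  })
  structure(list(patch_size_px = patch_size_px, stride_px = stride_px,
                 origins = origins, patches = patches, meta = meta),
            class = "patch_grid")
}

#' Reference palette classifier for synthetic fixtures
#'
#' Synthetic RGB fixtures are painted with three fixed nominal colors (tumor
#' red, stroma green, background blue) plus white glass. The reference
#' classifier assigns every pixel of a tile to its nearest palette color
#' (white counts as background) and returns the tile's class fractions as a
#' probability vector `(background, tumor, stroma)`. It exists so the
#' patch-classification plumbing is testable without a trained network; any
#' callable with the same contract can be plugged in instead.
#'
#' @format A list with the palette (`palette`, 4 x 3 RGB rows named
#'   background/tumor/stroma/glass) and the classifier function (`fn`).
#' @export
FIXTURE_PALETTE <- rbind(
  background = c(70L, 70L, 200L),
  tumor      = c(200L, 60L, 60L),
  stroma     = c(90L, 170L, 90L),
  glass      = c(255L, 255L, 255L)
)

#' @rdname FIXTURE_PALETTE
#' @param tile RGB array `(h, w, 3)`.
#' @return Numeric length-3 probability vector (background, tumor, stroma).
#' @export
palette_classifier <- function(tile) {
  px <- cbind(as.vector(tile[, , 1]), as.vector(tile[, , 2]),
              as.vector(tile[, , 3]))
  d2 <- vapply(seq_len(nrow(FIXTURE_PALETTE)), function(k) {
    rowSums(sweep(px, 2L, FIXTURE_PALETTE[k, ])^2)
  }, numeric(nrow(px)))
  cls <- max.col(-d2, ties.method = "first")  # 1 bg, 2 tumor, 3 stroma, 4 glass
  cls[cls == 4L] <- 1L                        # glass is background
  n <- length(cls)
  c(sum(cls == 1L), sum(cls == 2L), sum(cls == 3L)) / n
}

#' Classify patches and stitch per-class probability rasters
#'
#' Applies a patch classifier to every tile of a [extract_patches()] grid and
#' accumulates each tile's probability vector uniformly over its footprint;
#' where tiles overlap, contributions are averaged per pixel (sum of vectors
#' divided by coverage counts).
#'
#' @param grid a `patch_grid`.
#' @param classifier function mapping an RGB tile to a length-3 probability
#'   vector `(background, tumor, stroma)` summing to 1.
#' @return An object of class `probability_map`: rasters `background`,
#'   `tumor`, `stroma`, a `counts` raster (patches covering each pixel), and
#'   the slide `meta`.
#' @export
classify_patches <- function(grid, classifier = palette_classifier) {
  H <- grid$meta$height_px; W <- grid$meta$width_px
  ps <- grid$patch_size_px
  acc <- list(background = matrix(0, H, W), tumor = matrix(0, H, W),
              stroma = matrix(0, H, W))
  counts <- matrix(0L, H, W)
  for (i in seq_len(nrow(grid$origins))) {
    p <- classifier(grid$patches[[i]])
    if (!is.numeric(p) || length(p) != 3L || any(p < -1e-9) ||
        abs(sum(p) - 1) > 1e-6)
      contract_error("classifier output is not a 3-class probability vector")
    r <- grid$origins[i, 1]; c0 <- grid$origins[i, 2]
    ri <- (r + 1L):(r + ps); ci <- (c0 + 1L):(c0 + ps)
    acc$background[ri, ci] <- acc$background[ri, ci] + p[1]
    acc$tumor[ri, ci]      <- acc$tumor[ri, ci] + p[2]
    acc$stroma[ri, ci]     <- acc$stroma[ri, ci] + p[3]
    counts[ri, ci] <- counts[ri, ci] + 1L
  }
  covered <- counts > 0L
  for (nm in names(acc)) acc[[nm]][covered] <- acc[[nm]][covered] / counts[covered]
  structure(c(acc, list(counts = counts, meta = grid$meta)),
            class = "probability_map")
}

#' Convert a probability map to a class map by per-pixel argmax
#'
#' Pixels covered by at least one patch get the label of their most probable
#' class; exact ties resolve to the lowest class code (background wins over
#' tumor wins over stroma — conservative, keeps ambiguous tissue out of TSR
#' tallies). Uncovered pixels become NODATA.
#'
#' @param probs a `probability_map`.
#' @param meta optional [slide_meta()] override (defaults to `probs$meta`).
#' @return A [class_map()].
#' @export
stitch_to_classmap <- function(probs, meta = probs$meta) {
  H <- meta$height_px; W <- meta$width_px
  flat <- cbind(as.vector(probs$background), as.vector(probs$tumor),
                as.vector(probs$stroma))
  codes <- c(CLASS_CODES[["BACKGROUND"]], CLASS_CODES[["TUMOR"]],
             CLASS_CODES[["STROMA"]])
  lab <- matrix(codes[max.col(flat, ties.method = "first")], H, W)
  lab[probs$counts == 0L] <- CLASS_CODES[["NODATA"]]
  class_map(lab, meta)
}

#' Train a small color-feature baseline patch classifier
#'
#' A demonstration stand-in for an external CNN: multinomial logistic
#' regression (ridge-regularized, via glmnet is not required — plain
#' least-squares softmax would be overkill here) on per-tile color summaries
#' (channel means and standard deviations). Intended for synthetic fixtures
#' and plumbing demos, not histology-grade segmentation.
#'
#' @param tiles list of RGB tiles.
#' @param labels integer vector of class indices (1 = background, 2 = tumor,
#'   3 = stroma) aligned with `tiles`.
#' @return A function with the [classify_patches()] classifier contract.
#' @export
train_baseline_classifier <- function(tiles, labels) {
  if (length(tiles) != length(labels) || length(tiles) < 6L)
    parameter_error("need >= 6 labeled tiles covering the classes")
  feat <- t(vapply(tiles, tile_features, numeric(6)))
  labels <- as.integer(labels)
  # one-vs-rest logistic fits; probabilities renormalized to sum to 1
  fits <- lapply(1:3, function(k) {
    y <- as.integer(labels == k)
    suppressWarnings(stats::glm.fit(cbind(1, feat), y,
                                    family = stats::binomial()))$coefficients
  })
  function(tile) {
    x <- c(1, tile_features(tile))
    eta <- vapply(fits, function(b) sum(b * x, na.rm = TRUE), numeric(1))
    p <- stats::plogis(eta)
    if (sum(p) <= 0) p <- rep(1 / 3, 3)
    p / sum(p)
  }
}

tile_features <- function(tile) {
  c(mean(tile[, , 1]), mean(tile[, , 2]), mean(tile[, , 3]),
    stats::sd(tile[, , 1]), stats::sd(tile[, , 2]), stats::sd(tile[, , 3]))
}

#' Render a class map as a synthetic RGB image in the fixture palette
#'
#' Inverse of the reference classifier's palette lookup: tumor, stroma and
#' background pixels get their nominal colors, NODATA renders as glass white.
#' Used to build RGB fixtures whose segmentation ground truth is known.
#'
#' @param cm a [class_map()].
#' @return RGB array `(H, W, 3)` of integers 0..255.
#' @export
render_classmap_rgb <- function(cm) {
  H <- nrow(cm$labels); W <- ncol(cm$labels)
  arr <- array(255L, c(H, W, 3L))
  paint <- function(code, rgb) {
    idx <- cm$labels == code
    for (ch in 1:3) {
      plane <- arr[, , ch]; plane[idx] <- rgb[ch]; arr[, , ch] <<- plane
    }
  }
  paint(CLASS_CODES[["BACKGROUND"]], FIXTURE_PALETTE["background", ])
  paint(CLASS_CODES[["TUMOR"]], FIXTURE_PALETTE["tumor", ])
  paint(CLASS_CODES[["STROMA"]], FIXTURE_PALETTE["stroma", ])
  arr
}
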