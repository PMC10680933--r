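#' Tissue class codes
#'
#' Integer label codes used in every class map: background (glass plus
#' necrosis, adipose tissue, psammoma bodies and vessels), tumor epithelium,
#' tumor stroma, and a no-data code for unscanned or excluded area that all
#' tallies ignore.
#'
#' @export
CLASS_CODES <- c(BACKGROUND = 0L, TUMOR = 1L, STROMA = 2L, NODATA = 255L)

#' Slide metadata
#'
#' Physical metadata of a (virtual) slide: an identifier, the isotropic
#' resolution in micrometers per pixel, and the pixel dimensions. The physical
#' width in micrometers is `width_px * mpp`, recoverable exactly.
#'
#' @param slide_id opaque string identifying the slide.
#' @param mpp micrometers per pixel (isotropic), positive.
#' @param width_px,height_px raster dimensions in pixels.
#' @param magnification_label optional label such as `"20x"` or `"40x"`.
#' @return An object of class `slide_meta`.
#' @examples
#' slide_meta("s1", mpp = 0.25, width_px = 4000, height_px = 3000, "40x")
#' @export
slide_meta <- function(slide_id, mpp, width_px, height_px,
                       magnification_label = NULL) {
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    parameter_error("mpp must be a single positive number")
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (is.na(width_px) || width_px < 1L || is.na(height_px) || height_px < 1L)
    parameter_error("width_px and height_px must be integers >= 1")
  structure(
    list(slide_id = as.character(slide_id), mpp = as.numeric(mpp),
         width_px = width_px, height_px = height_px,
         magnification_label = magnification_label),
    class = "slide_meta"
  )
}

#' @export
print.slide_meta <- function(x, ...) {
  cat(sprintf("<slide_meta> %s: %d x %d px @ %g um/px%s\n", x$slide_id,
              x$width_px, x$height_px, x$mpp,
              if (is.null(x$magnification_label)) ""
              else paste0(" (", x$magnification_label, ")")))
  invisible(x)
}

#' Tissue class map
#'
#' A 2-D integer label raster over a slide, using the codes in
#' [CLASS_CODES], together with its [slide_meta()]. The class map is the
#' substrate of all downstream geometry: region-of-measurement search and
#' TSR tallies operate on it directly.
#'
#' @param labels integer matrix (rows = `meta$height_px`,
#'   cols = `meta$width_px`) containing only the codes 0, 1, 2, 255.
#' @param meta a [slide_meta()].
#' @return An object of class `class_map` with elements `labels` and `meta`.
#' @export
class_map <- function(labels, meta) {
  if (!inherits(meta, "slide_meta")) parameter_error("meta must be a slide_meta")
  if (!is.matrix(labels)) parameter_error("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (nrow(labels) != meta$height_px || ncol(labels) != meta$width_px)
    size_error(sprintf("labels is %d x %d but meta says %d x %d",
                       nrow(labels), ncol(labels),
                       meta$height_px, meta$width_px))
  bad <- !(labels %in% CLASS_CODES)
  if (any(bad))
    parameter_error(sprintf("labels contains %d pixels outside the codes {0,1,2,255}",
                            sum(bad)))
  structure(list(labels = labels, meta = meta), class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- tabulate_classes(x)
  cat(sprintf("<class_map> %s: %d x %d px @ %g um/px\n", x$meta$slide_id,
              x$meta$width_px, x$meta$height_px, x$meta$mpp))
  cat(sprintf("  tumor %d px, stroma %d px, background %d px, nodata %d px\n",
              tab[["TUMOR"]], tab[["STROMA"]], tab[["BACKGROUND"]],
              tab[["NODATA"]]))
  invisible(x)
}

tabulate_classes <- function(cm) {
  vapply(CLASS_CODES, function(code) sum(cm$labels == code), integer(1))
}

#' Downsample a class map by majority vote
#'
#' Reduces resolution by an integer factor `k`: each `k x k` block becomes one
#' pixel labeled with the block's modal class (ties resolve to the lowest
#' class code). Trailing rows/columns that do not fill a block are dropped.
#' The metadata `mpp` is multiplied by `k`.
#'
#' @param cm a [class_map()].
#' @param k integer downsampling factor >= 1.
#' @return A [class_map()] at `k`-fold coarser resolution.
#' @export
downsample_classmap <- function(cm, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) parameter_error("k must be an integer >= 1")
  if (k == 1L) return(cm)
  H <- nrow(cm$labels) %/% k; W <- ncol(cm$labels) %/% k
  if (H < 1L || W < 1L) size_error("downsampling factor exceeds map size")
  sub <- cm$labels[seq_len(H * k), seq_len(W * k), drop = FALSE]
  # per-class block counts via one matrix fold per class; argmax with
  # ties to the lowest code (code order below is ascending)
  codes <- sort(CLASS_CODES)
  counts <- vapply(codes, function(code) {
    m <- matrix(as.integer(sub == code), nrow = H * k)
    # fold rows into blocks, then columns
    m2 <- rowsum(m, rep(seq_len(H), each = k))
    t(rowsum(t(m2), rep(seq_len(W), each = k)))
  }, matrix(0L, H, W))
  flat <- matrix(counts, nrow = H * W, ncol = length(codes))
  lab <- matrix(codes[max.col(flat, ties.method = "first")], H, W)
  meta <- cm$meta
  meta$mpp <- meta$mpp * k
  meta$width_px <- W; meta$height_px <- H
  class_map(lab, meta)
}

#' Write / read a class map as plain-text PGM with a JSON sidecar
#'
#' Class maps are serialized as ASCII netpbm PGM (`P2`, maxval 255) so they
#' remain auditable text, with a JSON sidecar (same basename, `.json`)
#' carrying `slide_id`, `mpp`, `width_px`, `height_px`. The round trip is
#' bit-exact on labels and metadata.
#'
#' @param cm a [class_map()].
#' @param path output `.pgm` path.
#' @return `write_classmap` returns `path` invisibly; `read_classmap` returns
#'   the reconstructed [class_map()].
#' @export
write_classmap <- function(cm, path) {
  write_pgm(cm$labels, path, maxval = 255L)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  meta <- cm$meta
  jsonlite::write_json(
    list(slide_id = meta$slide_id, mpp = meta$mpp,
         width_px = meta$width_px, height_px = meta$height_px),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classmap
#' @export
read_classmap <- function(path) {
  labels <- read_pgm(path)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  if (!file.exists(sidecar)) data_error(paste("missing JSON sidecar:", sidecar))
  js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  class_map(labels, slide_meta(js$slide_id, js$mpp, js$width_px, js$height_px))
}

# --- minimal ASCII netpbm I/O (no raster-image package in this toolchain) ---

write_pgm <- function(mat, path, maxval = 255L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  # row-major pixel stream, wrapped one image row per line
  apply(mat, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") data_error("not an ASCII PGM (P2) file")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) data_error("PGM pixel count does not match header")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_ppm <- function(arr, path) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] == 3L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(dim(arr)[2], dim(arr)[1]), "255"), con)
  for (i in seq_len(dim(arr)[1])) {
    rgb <- rbind(arr[i, , 1], arr[i, , 2], arr[i, , 3])
    writeLines(paste(as.integer(rgb), collapse = " "), con)
  }
  invisible(path)
}

read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") data_error("not an ASCII PPM (P3) file")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != 3L * w * h) data_error("PPM pixel count does not match header")
  px <- matrix(vals, ncol = 3L, byrow = TRUE)  # row-major pixels
  arr <- array(0L, c(h, w, 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(px[, ch], nrow = h, byrow = TRUE)
  arr
}
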