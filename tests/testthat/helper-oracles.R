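# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-pixel loops over explicit disk offsets) so they
# cannot share a bug with the optimized implementation paths they check.

# Explicit (dy, dx) offsets of a pixel-centered disk.
disk_offsets <- function(radius_px) {
  R <- floor(radius_px)
  off <- expand.grid(dy = -R:R, dx = -R:R)
  off[off$dy^2 + off$dx^2 <= radius_px^2, ]
}

# Brute-force sum of `mat` over the clipped disk around (r, c).
brute_disk_sum <- function(mat, r, c, off) {
  rr <- r + off$dy; cc <- c + off$dx
  ok <- rr >= 1 & rr <= nrow(mat) & cc >= 1 & cc <= ncol(mat)
  sum(mat[cbind(rr[ok], cc[ok])])
}

# Brute-force most-invasive FOV search over an explicit center grid,
# re-implementing the scoring and tie rules from first principles.
brute_mi_search <- function(cm, radius_um, stride_px, min_tissue_fraction = 2 / 3) {
  lab <- cm$labels
  radius_px <- radius_um / cm$meta$mpp
  off <- disk_offsets(radius_px)
  is_t <- lab == 1L; is_s <- lab == 2L
  inb <- matrix(TRUE, nrow(lab), ncol(lab))   # in-bounds disk area
  best <- NULL
  for (r in seq.int(1L, nrow(lab), by = stride_px)) {
    for (c in seq.int(1L, ncol(lab), by = stride_px)) {
      tn <- brute_disk_sum(is_t, r, c, off)
      sn <- brute_disk_sum(is_s, r, c, off)
      nn <- brute_disk_sum(inb, r, c, off)
      if (tn + sn == 0 || nn == 0) next
      tissue_fr <- (tn + sn) / nn
      if (tissue_fr <= min_tissue_fraction) next
      tumor_fr <- tn / (tn + sn)
      if (is.null(best) || tumor_fr > best$tumor_fraction + 1e-12 ||
          (abs(tumor_fr - best$tumor_fraction) <= 1e-12 &&
           tissue_fr > best$tissue_fraction + 1e-12)) {
        best <- list(center = c(row = r, col = c), tumor_fraction = tumor_fr,
                     tissue_fraction = tissue_fr)
      }
    }
  }
  best
}

# Hand log-rank chi-square for two groups by summing hypergeometric O-E
# terms over the distinct event times (events precede censorings at ties).
hand_logrank_chi2 <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  o <- e <- v <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at_risk <- times >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(events == 1 & times == tt)
    d1 <- sum(events == 1 & times == tt & grp == 1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Uniform class map fixture.
uniform_map <- function(code, H = 32, W = 32, mpp = 100, id = "fix") {
  class_map(matrix(as.integer(code), H, W), slide_meta(id, mpp, W, H))
}

# Disk phantom: tumor disk of radius_px centered in a stroma field.
tumor_disk_phantom <- function(H, W, mpp, radius_px, id = "phantom") {
  lab <- matrix(CLASS_CODES[["STROMA"]], H, W)
  d <- tsrquant:::disk_mask(H, W, (H + 1) / 2, (W + 1) / 2, radius_px)
  lab[d] <- CLASS_CODES[["TUMOR"]]
  class_map(lab, slide_meta(id, mpp, W, H))
}
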