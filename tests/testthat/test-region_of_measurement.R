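test_that("uniform all-tumor map: fraction 1, first row-major grid center wins", {
  cm <- uniform_map(CLASS_CODES[["TUMOR"]], H = 40, W = 40, mpp = 100)
  res <- find_most_invasive_fov(cm, radius_um = 1600, stride_px = 8)
  expect_equal(res$fov$tumor_fraction, 1.0)
  expect_equal(unname(res$fov$center), c(1, 1))  # tie rule: row-major first
  expect_s3_class(res$rom, "region_of_measurement")
  expect_equal(res$rom$kind, "MI")
})

test_that("MI search equals the brute-force argmax on a two-blob map", {
  # one pure-tumor blob and one 50/50 blob; exhaustive stride-1 oracle
  lab <- matrix(CLASS_CODES[["STROMA"]], 64, 64)
  blob1 <- tsrquant:::disk_mask(64, 64, 16, 16, 10)
  lab[blob1] <- CLASS_CODES[["TUMOR"]]
  blob2 <- tsrquant:::disk_mask(64, 64, 48, 48, 10)
  mix <- which(blob2)
  lab[mix[seq_along(mix) %% 2 == 0]] <- CLASS_CODES[["TUMOR"]]
  cm <- class_map(lab, slide_meta("blobs", 100, 64, 64))
  res <- find_most_invasive_fov(cm, radius_um = 1600, stride_px = 1)
  oracle <- brute_mi_search(cm, 1600, 1)
  expect_equal(unname(res$fov$center), unname(oracle$center))
  expect_equal(res$fov$tumor_fraction, oracle$tumor_fraction)
})

test_that("maps without a valid field of view raise the right conditions", {
  # thin tumor rim on mostly background: every disk fails the 2/3 tissue rule
  lab <- matrix(CLASS_CODES[["BACKGROUND"]], 48, 48)
  lab[24, ] <- CLASS_CODES[["TUMOR"]]
  cm <- class_map(lab, slide_meta("rim", 100, 48, 48))
  expect_error(find_most_invasive_fov(cm, 1600, stride_px = 4),
               class = "tsrq_no_valid_fov_error")
  expect_error(find_most_invasive_fov(uniform_map(CLASS_CODES[["NODATA"]]),
                                      1600, 4),
               class = "tsrq_empty_map_error")
  expect_error(find_most_invasive_fov(uniform_map(CLASS_CODES[["BACKGROUND"]]),
                                      1600, 4),
               class = "tsrq_empty_map_error")
})

test_that("MI search is translation-equivariant", {
  # tumor blob well inside a stroma field, so the winning disk stays in bounds
  lab <- matrix(CLASS_CODES[["STROMA"]], 96, 96)
  lab[tsrquant:::disk_mask(96, 96, 48, 48, 20)] <- CLASS_CODES[["TUMOR"]]
  base <- class_map(lab, slide_meta("base", 50, 96, 96))
  dr <- 7L; dc <- 5L
  shifted <- matrix(CLASS_CODES[["NODATA"]], 96 + dr, 96 + dc)
  shifted[(dr + 1):(96 + dr), (dc + 1):(96 + dc)] <- base$labels
  cms <- class_map(shifted, slide_meta("shift", 50, 96 + dc, 96 + dr))
  r0 <- find_most_invasive_fov(base, 1600, stride_px = 1)
  r1 <- find_most_invasive_fov(cms, 1600, stride_px = 1)
  expect_equal(unname(r1$fov$center), unname(r0$fov$center) + c(dr, dc))
})

test_that("local tumor density matches definitions on uniform and point maps", {
  expect_true(all(local_tumor_density(uniform_map(CLASS_CODES[["TUMOR"]]),
                                      500)$values == 1))
  expect_true(all(local_tumor_density(uniform_map(CLASS_CODES[["STROMA"]]),
                                      500)$values == 0))
  # single tumor pixel: density at the center is 1 / (disk pixel count)
  cm <- uniform_map(CLASS_CODES[["STROMA"]], H = 21, W = 21, mpp = 100)
  cm$labels[11, 11] <- CLASS_CODES[["TUMOR"]]
  k <- nrow(disk_offsets(500 / 100))
  d <- local_tumor_density(cm, 500)
  expect_equal(d$values[11, 11], 1 / k)
  expect_error(local_tumor_density(cm, 50), class = "tsrq_parameter_error")
})

test_that("density field matches brute-force disk counting at borders", {
  g <- generate_mask(mask_spec(width_px = 48, height_px = 48, mpp = 100,
                               seed = 33))
  d <- local_tumor_density(g$classmap, 700)
  off <- disk_offsets(7)
  is_t <- g$classmap$labels == CLASS_CODES[["TUMOR"]]
  is_n <- g$classmap$labels != CLASS_CODES[["NODATA"]]
  for (p in list(c(1, 1), c(1, 25), c(24, 24), c(48, 3), c(10, 48))) {
    expect_equal(d$values[p[1], p[2]],
                 brute_disk_sum(is_t, p[1], p[2], off) /
                   brute_disk_sum(is_n, p[1], p[2], off))
  }
})

test_that("dynamic threshold is the stated piecewise-linear form", {
  expect_equal(dynamic_threshold(50, 0.2, 0.6, 50), 0.2)    # A = area_ref
  expect_equal(dynamic_threshold(120, 0.2, 0.6, 50), 0.2)   # large tumor
  expect_equal(dynamic_threshold(0, 0.2, 0.6, 50), 0.6)     # A = 0
  expect_equal(dynamic_threshold(25, 0.2, 0.6, 50), 0.4)    # midpoint
  a <- seq(0, 60, by = 5)
  taus <- vapply(a, dynamic_threshold, numeric(1), tau_base = 0.2,
                 tau_max = 0.6, area_ref_mm2 = 50)
  expect_true(all(diff(taus) <= 0))                          # non-increasing
  expect_error(dynamic_threshold(-1, 0.2, 0.6, 50),
               class = "tsrq_parameter_error")
  expect_error(dynamic_threshold(1, 0.7, 0.6, 50),
               class = "tsrq_parameter_error")
})

test_that("tumor bed covers everything on an all-tumor map and errors correctly", {
  cm <- uniform_map(CLASS_CODES[["TUMOR"]], H = 40, W = 40, mpp = 100)
  rom <- estimate_tumor_bed(cm, 500, tau_base = 0.5, tau_max = 0.5,
                            min_component_mm2 = 0)
  expect_true(all(rom$mask))
  expect_error(estimate_tumor_bed(uniform_map(CLASS_CODES[["STROMA"]]), 500),
               class = "tsrq_no_tumor_error")
  # single tumor pixel in a stroma field: no pixel clears a high threshold
  lone <- uniform_map(CLASS_CODES[["STROMA"]], H = 40, W = 40, mpp = 100)
  lone$labels[20, 20] <- CLASS_CODES[["TUMOR"]]
  expect_error(estimate_tumor_bed(lone, 500, tau_base = 0.9, tau_max = 0.9,
                                  min_component_mm2 = 0),
               class = "tsrq_empty_rom_error")
})

test_that("tumor-bed area shrinks as the threshold rises, against brute-force density", {
  cm <- tumor_disk_phantom(120, 120, 20, radius_px = 50)  # 2 mm tumor disk
  areas <- vapply(c(0.1, 0.3, 0.5), function(tb) {
    sum(estimate_tumor_bed(cm, 500, tau_base = tb, tau_max = tb,
                           min_component_mm2 = 0)$mask)
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
  # spot-check the underlying density against naive disk counting
  d <- local_tumor_density(cm, 500)
  off <- disk_offsets(25)
  is_t <- cm$labels == CLASS_CODES[["TUMOR"]]
  inb <- matrix(TRUE, 120, 120)
  for (p in list(c(60, 60), c(60, 10), c(35, 60))) {
    expect_equal(d$values[p[1], p[2]],
                 brute_disk_sum(is_t, p[1], p[2], off) /
                   brute_disk_sum(inb, p[1], p[2], off))
  }
})

test_that("WT monotonicity: ROM(tau1) contains ROM(tau2) for tau1 <= tau2", {
  g <- generate_mask(mask_spec(width_px = 160, height_px = 160, mpp = 25,
                               seed = 9))
  taus <- c(0.1, 0.25, 0.4, 0.6)
  masks <- lapply(taus, function(tau)
    estimate_tumor_bed(g$classmap, 500, tau_base = tau, tau_max = tau,
                       min_component_mm2 = 0)$mask)
  for (i in seq_len(length(taus) - 1))
    expect_true(all(masks[[i]][masks[[i + 1]]]))
})

test_that("small components are removed from the tumor bed", {
  # main tumor disk plus a small tumor speck far away
  cm <- tumor_disk_phantom(100, 100, 20, radius_px = 25)
  speck <- tsrquant:::disk_mask(100, 100, 10, 10, 4)
  cm$labels[speck] <- CLASS_CODES[["TUMOR"]]
  with_speck <- estimate_tumor_bed(cm, 100, tau_base = 0.4, tau_max = 0.4,
                                   min_component_mm2 = 0)
  filtered <- estimate_tumor_bed(cm, 100, tau_base = 0.4, tau_max = 0.4,
                                 min_component_mm2 = 0.05)
  expect_true(with_speck$mask[10, 10])
  expect_false(filtered$mask[10, 10])
  expect_true(filtered$mask[50, 50])
})

test_that("ROM round trip preserves mask and parameters", {
  g <- generate_mask(mask_spec(width_px = 64, height_px = 64, mpp = 100,
                               seed = 2))
  rom <- estimate_tumor_bed(g$classmap, 500)
  path <- file.path(withr::local_tempdir(), "rom.pgm")
  write_rom(rom, path)
  back <- read_rom(path)
  expect_identical(back$mask, rom$mask)
  expect_equal(back$kind, "WT")
  expect_equal(back$params$tau, rom$params$tau)
})
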