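rgb_image <- function(r, g, b, res = 1000, role = "endothelial") {
  arr <- array(0, c(nrow(r), ncol(r), 3))
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  calibrated_image(arr, res, role)
}

disk_mask <- function(nx, cx, cy, r) {
  g <- expand.grid(x = 0:(nx - 1), y = 0:(nx - 1))
  matrix(sqrt((g$x - cx)^2 + (g$y - cy)^2) <= r, nx, nx)
}

test_that("HSB threshold selects by hue, saturation and brightness", {
  z <- matrix(0, 64, 64); one <- matrix(1, 64, 64)
  green <- rgb_image(z, one, z)
  expect_true(all(hsb_threshold(green, c(90, 150), blur_sigma_px = 0)))
  red <- rgb_image(one, z, z)
  expect_false(any(hsb_threshold(red, c(90, 150), blur_sigma_px = 0)))
  # wrap-around hue interval catches red
  expect_true(all(hsb_threshold(red, c(330, 30), blur_sigma_px = 0)))
  # grayscale input is rejected
  gray <- calibrated_image(matrix(0.5, 64, 64), 1000, "endothelial")
  expect_error(hsb_threshold(gray), "RGB")
})

test_that("thresholded green disks match the drawn disks", {
  nx <- 96
  dm <- disk_mask(nx, 30, 30, 8) | disk_mask(nx, 70, 60, 6)
  g <- matrix(0, nx, nx); g[dm] <- 0.9
  img <- rgb_image(matrix(0, nx, nx), g, matrix(0, nx, nx))
  got <- hsb_threshold(img, c(90, 150), bright_min = 0.2, blur_sigma_px = 1)
  mismatch <- which(got != dm, arr.ind = TRUE)
  if (nrow(mismatch) > 0) {
    d1 <- sqrt((mismatch[, 1] - 1 - 30)^2 + (mismatch[, 2] - 1 - 30)^2) - 8
    d2 <- sqrt((mismatch[, 1] - 1 - 70)^2 + (mismatch[, 2] - 1 - 60)^2) - 6
    expect_true(all(pmin(abs(d1), abs(d2)) <= 1.5))  # blur-induced edge band
  } else {
    succeed()
  }
})

test_that("the minimal area gate drops sub-threshold capillaries", {
  nx <- 64                               # 1 um/px
  m <- matrix(FALSE, nx, nx)
  m[10, 10] <- TRUE                      # 1 px = 1.0 um^2: dropped
  m[30, 30] <- TRUE; m[31, 30] <- TRUE   # 2 px = 2.0 um^2: kept
  caps <- detect_capillaries(m, 1000, min_area_um2 = 1.5)
  expect_equal(nrow(caps), 1)
  expect_equal(caps$area_um2, 2.0)
  # gate monotonicity
  for (gate in c(0.5, 1.5, 2.5)) {
    n_at <- nrow(detect_capillaries(m, 1000, min_area_um2 = gate))
    expect_true(n_at <= nrow(detect_capillaries(m, 1000, min_area_um2 = 0)))
  }
})

test_that("circularity separates transverse disks from longitudinal bars", {
  disk <- disk_mask(64, 32, 32, 10)
  caps <- detect_capillaries(disk, 1000)
  expect_equal(nrow(caps), 1)
  expect_gte(caps$circularity, 0.9)
  expect_true(caps$transverse)
  expect_lt(abs(caps$min_feret_um - 20), 1.5)

  bar <- matrix(FALSE, 64, 64); bar[10:12, 10:49] <- TRUE   # 3 x 40 px
  got <- detect_capillaries(bar, 1000)
  expect_equal(nrow(got), 1)                # counted ...
  expect_lt(got$circularity, 0.35)
  expect_false(got$transverse)              # ... but not sized
  expect_true(is.na(got$min_feret_um))
})

test_that("digitised disk circularity converges to 1 with radius", {
  # unclamped 4 pi A / P^2 (reported circularity is capped at 1)
  ratio <- vapply(c(5, 20, 80), function(r) {
    m <- disk_mask(2 * r + 12, r + 5, r + 5, r)
    4 * pi * sum(m) / cardiohist:::chain_perimeter(m)^2
  }, numeric(1))
  expect_true(all(diff(abs(ratio - 1)) < 0))
  expect_lt(abs(ratio[3] - 1), 0.03)
})

test_that("fibroblast counting subtracts endothelial cross-reactivity", {
  nx <- 96
  z <- matrix(FALSE, nx, nx)
  vim <- z
  centers <- cbind(c(15, 40, 65, 20, 50, 75, 30, 60, 85, 10),
                   c(15, 20, 25, 50, 55, 60, 80, 85, 88, 70))
  for (i in 1:10) vim <- vim | disk_mask(nx, centers[i, 1], centers[i, 2], 2)
  endo <- z
  for (i in 1:4) endo <- endo | disk_mask(nx, centers[i, 1], centers[i, 2], 3)
  # 4 of 10 blobs coincide with capillaries and are erased entirely
  fb <- fibroblast_count(vim, endo, 1000, min_area_um2 = 1.5)
  expect_equal(nrow(fb), 6)
  # identical masks: full subtraction
  expect_equal(nrow(fibroblast_count(vim, vim, 1000)), 0)
  # disjoint masks: nothing subtracted
  expect_equal(nrow(fibroblast_count(vim, z, 1000)), 10)
  expect_error(fibroblast_count(vim, matrix(FALSE, 10, 10), 1000), "shapes")
})

test_that("densities are exact count ratios with undefined zero-myocyte case", {
  d <- densities(60, 0, 100, image_area_mm2 = 0.5)
  expect_equal(d$capillaries_per_myocyte, 0.6)
  expect_equal(d$fibroblasts_per_myocyte, 0)
  expect_equal(d$capillaries_per_mm2, 120)
  expect_true(is.na(densities(5, 5, 0)$capillaries_per_myocyte))
})

test_that("synthetic capillary and fibroblast densities are recovered", {
  tis <- generate_tissue(synthetic_spec(seed = 17))
  cfg <- analysis_config()
  emask <- hsb_threshold(tis$endothelial, cfg$hsb_hue_range_deg,
                         cfg$hsb_sat_min, cfg$hsb_bright_min, cfg$blur_sigma_px)
  caps <- detect_capillaries(emask, 2000)
  expect_equal(nrow(caps), nrow(tis$truth$capillaries))
  fmask <- hsb_threshold(tis$fibroblast, cfg$hsb_hue_range_fibro_deg,
                         cfg$hsb_sat_min, cfg$hsb_bright_min, cfg$blur_sigma_px)
  fb <- fibroblast_count(fmask, emask, 2000)
  expect_equal(nrow(fb), tis$truth$n_true_fibroblasts)
})
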