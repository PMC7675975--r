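test_that("calibration converts pixels to micrometres", {
  img <- calibrated_image(matrix(0.5, 512, 512), 2000, "wga", "t")
  expect_equal(pixel_size_um(img), 0.5)
  expect_error(calibrated_image(matrix(0.5, 64, 64), -1, "wga"), "positive")
  expect_error(calibrated_image(matrix(0.5, 10, 64), 1000, "wga"), "64 x 64")
})

test_that("images load deterministically across formats and bit depths", {
  scene <- generate_tissue(synthetic_spec(seed = 8, image_px = c(128L, 128L),
                                          n_cells = 18L))$wga$pixels
  tmp <- withr::local_tempdir()
  p8 <- file.path(tmp, "scene8.tif")
  p16 <- file.path(tmp, "scene16.tif")
  ppng <- file.path(tmp, "scene.png")
  pbmp <- file.path(tmp, "scene.bmp")
  write_image(scene, p8, bits_per_sample = 8)
  write_image(scene, p16, bits_per_sample = 16)
  write_image(scene, ppng)
  write_bmp24(scene, pbmp)

  a <- load_channel(p8, 2000, "wga")
  b <- load_channel(p8, 2000, "wga")
  expect_identical(a$pixels, b$pixels)

  # 8- vs 16-bit of the same float scene: masks agree after per-image
  # normalisation except for borderline pixels on the one-pixel
  # anti-aliased membrane transition, where quantisation can flip the
  # strict comparison either way
  m8 <- phansalkar_threshold(load_channel(p8, 2000, "wga"))
  m16 <- phansalkar_threshold(load_channel(p16, 2000, "wga"))
  flips <- which(m8 != m16)
  expect_lt(length(flips) / length(m8), 0.02)
  expect_true(all(abs(scene[flips] - 0.5) < 0.45))  # all on the soft edge

  # PNG and BMP round-trips agree with the 8-bit TIFF to quantisation
  # (one grey level, rescaled by the per-image normalisation)
  expect_lt(max(abs(load_channel(ppng, 2000, "wga")$pixels - a$pixels)), 0.01)
  bmp <- load_channel(pbmp, 2000, "wga")
  expect_equal(dim(bmp$pixels)[1:2], dim(scene))
  expect_lt(max(abs(bmp$pixels[, , 1] - a$pixels)), 0.01)

  expect_error(load_channel(file.path(tmp, "missing.tif"), 1000, "wga"), "missing")
})

test_that("record CSVs round-trip numeric fields", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "rec.csv")
  set.seed(5)
  rec <- tibble::tibble(
    image_id = "img", myocyte_id = 1:3,
    centroid_x_px = runif(3, 0, 300), centroid_y_px = runif(3, 0, 300),
    area_um2 = runif(3, 20, 400), min_feret_um = runif(3, 5, 30),
    border_flag = c(TRUE, FALSE, FALSE)
  )
  write_records_csv(rec, path)
  expect_length(readLines(path), 4)   # header + 3 rows
  back <- read_records_csv(path)
  for (col in names(rec)) {
    if (is.numeric(rec[[col]])) {
      expect_equal(back[[col]], rec[[col]], tolerance = 1e-6)
    }
  }
  write_records_csv(rec[0, ], path)
  expect_length(readLines(path), 1)   # header only
})

test_that("overlays render the segmentation and the CDI colour map", {
  tmp <- withr::local_tempdir()
  img <- calibrated_image({
    px <- matrix(0.1, 96, 96); px[47:50, ] <- 0.9; px
  }, 1000, "wga")
  cfg <- analysis_config()
  mask <- phansalkar_threshold(img, config = cfg)
  seg <- detect_myocytes(img, mask, cfg)
  g <- measure_septa(build_neighbor_graph(seg, cfg$neighbor_min_contact_px),
                     img, mask, cfg)
  cdi <- compute_cdi(g, reference_stats(10, 1))   # nothing enhanced
  paths <- write_overlay(img, g, cdi, file.path(tmp, "img1"))
  expect_true(all(file.exists(paste0(file.path(tmp, "img1"),
                                     c("_overlay.png", "_cdi.png")))))
  # CDI all zero: cell fills are white
  heat <- png::readPNG(paste0(file.path(tmp, "img1"), "_cdi.png"))
  cells <- which(t(!mask))
  whites <- heat[, , 1][cells] == 1 & heat[, , 2][cells] == 1 & heat[, , 3][cells] == 1
  expect_gt(mean(whites), 0.95)

  bad <- calibrated_image(matrix(0.5, 64, 64), 1000, "wga")
  expect_error(write_overlay(bad, g, cdi, file.path(tmp, "bad")), "dimensions")
})

test_that("batch analysis matches channels, skips orphans and is deterministic", {
  tmp <- withr::local_tempdir()
  wd <- file.path(tmp, "wga"); ed <- file.path(tmp, "endo")
  dir.create(wd); dir.create(ed)
  for (s in 1:3) {
    tis <- generate_tissue(synthetic_spec(seed = s, image_px = c(192L, 192L),
                                          n_cells = 40L))
    write_image(tis$wga, file.path(wd, sprintf("img%d.tif", s)))
    if (s < 3) write_image(tis$endothelial, file.path(ed, sprintf("IMG%d.tif", s)))
  }
  out1 <- file.path(tmp, "out1"); out2 <- file.path(tmp, "out2")
  cfg <- analysis_config(n_permutations = 50L)
  expect_warning(
    s1 <- run_batch(wga_dir = wd, endothelial_dir = ed, out_dir = out1,
                    resolution_px_per_mm = 2000, config = cfg,
                    overlays = FALSE, progress = FALSE),
    "img3"
  )
  expect_equal(nrow(s1), 2)   # img3 has no endothelial partner
  expect_true(all(is.finite(s1$fibrosis_fraction)))
  expect_true(all(s1$myocyte_count > 0))
  expect_true(all(is.finite(s1$capillaries_per_myocyte)))
  expect_true(all(is.na(s1$fibroblast_count)))   # channel absent

  suppressWarnings(
    s2 <- run_batch(wga_dir = wd, endothelial_dir = ed, out_dir = out2,
                    resolution_px_per_mm = 2000, config = cfg,
                    overlays = FALSE, progress = FALSE)
  )
  for (f in c("summary.csv", "myocytes.csv", "septa.csv", "cdi.csv")) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }

  # summary medians equal the medians of the per-structure CSV columns
  myo <- read_records_csv(file.path(out1, "myocytes.csv"))
  sep <- read_records_csv(file.path(out1, "septa.csv"))
  for (id in s1$image_id) {
    keep <- myo$image_id == id & myo$size_ok
    expect_equal(s1$median_min_feret_um[s1$image_id == id],
                 median(myo$min_feret_um[keep]))
    expect_equal(s1$median_septum_width_um[s1$image_id == id],
                 median(sep$septum_width_um[sep$image_id == id]))
  }

  expect_error(run_batch(out_dir = tmp, resolution_px_per_mm = 1000),
               "at least one channel")
  empty <- file.path(tmp, "empty"); dir.create(empty)
  expect_error(run_batch(wga_dir = empty, out_dir = tmp, resolution_px_per_mm = 1000),
               "no images")
})

test_that("WGA-only batches flag vessel fields as absent", {
  tmp <- withr::local_tempdir()
  wd <- file.path(tmp, "wga")
  dir.create(wd)
  tis <- generate_tissue(synthetic_spec(seed = 9, image_px = c(192L, 192L),
                                        n_cells = 40L))
  write_image(tis$wga, file.path(wd, "only.tif"))
  s <- run_batch(wga_dir = wd, out_dir = file.path(tmp, "o"),
                 resolution_px_per_mm = 2000,
                 config = analysis_config(n_permutations = 50L),
                 overlays = FALSE, progress = FALSE)
  expect_equal(nrow(s), 1)
  expect_true(is.na(s$capillary_count))
  expect_true(is.na(s$capillaries_per_myocyte))
  expect_gt(s$myocyte_count, 30)
})

test_that("configuration survives a YAML round trip", {
  tmp <- withr::local_tempdir()
  cfg <- analysis_config(phansalkar_radius_px = 11L, reference_mu_um = 2.4,
                         reference_sd_um = 0.5, seed = 7L)
  p <- file.path(tmp, "cfg.yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("not_a_field: 3", p)
  expect_error(read_config(p), "unknown config fields")
})
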