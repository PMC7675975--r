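cfg <- analysis_config()

two_cell_stripe <- function(stripe_cols = 63:66, nx = 128, hi = 0.9) {
  px <- matrix(0.1, nx, nx)
  px[stripe_cols, ] <- hi
  calibrated_image(px, 1000, "wga")
}

test_that("a constructed stripe measures its own width", {
  img <- two_cell_stripe()           # 4 px stripe, 1 um/px
  mask <- phansalkar_threshold(img, config = cfg)
  seg <- detect_myocytes(img, mask, cfg)
  expect_equal(nrow(seg$records), 2)
  g <- build_neighbor_graph(seg, cfg$neighbor_min_contact_px)
  expect_equal(nrow(g$edges), 1)
  w <- septum_width(img, mask, g, g$edges$id_a[1], g$edges$id_b[1], cfg)
  expect_lt(abs(w - 4.0), 0.3)
  # symmetric in edge direction
  w2 <- septum_width(img, mask, g, g$edges$id_b[1], g$edges$id_a[1], cfg)
  expect_equal(w, w2)
  # no stained pixel on the profile -> zero width
  g0 <- measure_septa(g, img, matrix(FALSE, 128, 128), cfg)
  expect_equal(g0$edges$septum_width_um, 0)
  # unknown edge is an error
  expect_error(septum_width(img, mask, g, 1, 99, cfg), "not in the neighbour graph")
})

test_that("an interior cell of a hexagonal mosaic has six neighbours", {
  seeds <- as.matrix(expand.grid(i = 0:5, j = 0:6))
  seeds <- cbind(20 + seeds[, "i"] * 32 + 16 * (seeds[, "j"] %% 2),
                 14 + seeds[, "j"] * 28)
  vs <- voronoi_scene(seeds, 220, 220, width_px = 4)
  g <- build_neighbor_graph(seg_from_labels(vs$labels, seeds), 5L)
  centre <- which.min((seeds[, 1] - 110)^2 + (seeds[, 2] - 110)^2)
  deg <- sum(g$edges$id_a == centre) + sum(g$edges$id_b == centre)
  expect_equal(deg, 6)
})

test_that("region adjacency agrees with Delaunay adjacency of the seeds", {
  set.seed(12)
  for (rep in 1:3) {
    seeds <- cbind(runif(12, 15, 145), runif(12, 15, 145))
    while (min(dist(seeds)) < 18) seeds <- cbind(runif(12, 15, 145), runif(12, 15, 145))
    vs <- voronoi_scene(seeds, 160, 160, width_px = 3)
    g <- build_neighbor_graph(seg_from_labels(vs$labels, seeds), 5L)
    got <- paste(g$edges$id_a, g$edges$id_b)
    del <- oracle_delaunay_pairs(seeds)
    del_keys <- paste(pmin(del[, 1], del[, 2]), pmax(del[, 1], del[, 2]))
    # every detected neighbour pair is Delaunay-adjacent
    expect_true(all(got %in% del_keys))
    # Delaunay pairs with a substantial realised contact are all found
    lab <- vs$labels
    p4 <- rbind(cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ])),
                cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1])))
    p4 <- p4[p4[, 1] != p4[, 2], , drop = FALSE]
    cnt <- table(paste(pmin(p4[, 1], p4[, 2]), pmax(p4[, 1], p4[, 2])))
    strong <- names(cnt)[cnt >= 10]
    expect_true(all(strong[strong %in% del_keys] %in% got))
  }
})

test_that("reference statistics pool edges with sample SD", {
  expect_equal(unclass(estimate_reference(rep(3, 12)))[c("mu_um", "sd_um")],
               list(mu_um = 3, sd_um = 0))
  r <- estimate_reference(rep(c(2, 4), 500))
  expect_equal(r$mu_um, 3)
  expect_lt(abs(r$sd_um - 1), 0.01)
  expect_error(estimate_reference(c(1, 2, 3)), "at least 10")

  set.seed(99)
  big <- estimate_reference(rnorm(10000, 3, 0.5))
  expect_lt(abs(big$mu_um - 3), 0.02)
  expect_lt(abs(big$sd_um - 0.5), 0.02)
})

test_that("CDI is the fraction of enhanced incident septa", {
  # star: node 1 with 4 neighbours, two septa over threshold
  g <- make_graph(5, cbind(1, 2:5), widths = c(5, 5, 1, 1))
  ref <- reference_stats(2, 0.5)      # enhanced > 3
  cdi <- compute_cdi(g, ref)
  expect_equal(cdi$records$cdi[1], 0.5)
  expect_equal(cdi$records$n_enhanced[1], 2L)
  expect_equal(cdi$records$cdi[-1], c(1, 1, 0, 0))

  # all below threshold -> all zero
  g0 <- make_graph(5, cbind(1, 2:5), widths = rep(1, 4))
  expect_true(all(compute_cdi(g0, ref)$records$cdi == 0))

  # isolated node flagged undefined and excluded from the mean
  g2 <- make_graph(4, rbind(c(1, 2), c(2, 3)), widths = c(5, 1))
  out <- compute_cdi(g2, ref)
  expect_true(is.na(out$records$cdi[4]))
  expect_equal(out$mean_cdi, mean(c(1, 1 / 2, 0)))
})

test_that("CDI is monotone in any single edge width", {
  set.seed(21)
  for (rep in 1:10) {
    em <- random_graph(8, 0.4)
    if (nrow(em) == 0) next
    w <- runif(nrow(em), 1, 5)
    ref <- reference_stats(2, 0.5)
    base <- compute_cdi(make_graph(8, em, w), ref)$records$cdi
    e <- sample(nrow(em), 1)
    w2 <- w; w2[e] <- w2[e] + runif(1, 0, 5)
    up <- compute_cdi(make_graph(8, em, w2), ref)$records$cdi
    expect_true(all(up >= base - 1e-12, na.rm = TRUE))
  }
})

test_that("mean CDI hits its threshold limits", {
  g <- make_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)), widths = c(1, 2, 3))
  expect_equal(compute_cdi(g, reference_stats(100, 10))$mean_cdi, 0)
  expect_equal(compute_cdi(g, reference_stats(1e-9, 0))$mean_cdi, 1)
  gl <- glance(compute_cdi(g, reference_stats(1, 0.4)))  # enhanced > 1.8
  expect_equal(gl$frac_cdi_ge_50, mean(c(0, 1 / 2, 1, 1) >= 0.5))
})

test_that("recovered septum widths track ground truth on noise-free scenes", {
  tis <- generate_tissue(synthetic_spec(seed = 13))
  mask <- phansalkar_threshold(tis$wga, config = cfg)
  seg <- detect_myocytes(tis$wga, mask, cfg)
  g <- measure_septa(build_neighbor_graph(seg, cfg$neighbor_min_contact_px),
                     tis$wga, mask, cfg)
  m <- match_objects(tis$truth$cells[, c("seed_x_px", "seed_y_px")],
                     seg$records[, c("seed_x_px", "seed_y_px")], 14)
  map <- setNames(m$pairs$manual_id, m$pairs$auto_id)
  est <- dplyr::mutate(g$edges,
                       ta = pmin(map[as.character(id_a)], map[as.character(id_b)]),
                       tb = pmax(map[as.character(id_a)], map[as.character(id_b)]))
  j <- dplyr::inner_join(est, tis$truth$edges, by = c(ta = "id_a", tb = "id_b"))
  expect_gt(nrow(j), 200)
  err_px <- (j$septum_width_um - j$width_um) / pixel_size_um(tis$wga)
  expect_lte(mean(abs(err_px)), 0.5)
  expect_lt(abs(median(j$septum_width_um) / median(j$width_um) - 1), 0.05)
})
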