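#' Specification of a synthetic myocardium scene
#'
#' Parameters of the synthetic three-channel micrograph generator. The
#' defaults emulate transversely sectioned atrial myocardium imaged at
#' roughly 200-400x: 0.5 um pixels, ~16 um myocyte cross-sections,
#' endomysial septa of 2.5 um mean width, and capillary and fibroblast
#' densities around 0.6 and 0.5 per myocyte.
#'
#' @param image_px Width and height in pixels.
#' @param resolution_px_per_mm Spatial calibration.
#' @param n_cells Number of myocytes (Poisson-disk seeded Voronoi
#'   mosaic).
#' @param mean_cell_diameter_um Nominal myocyte diameter, controlling
#'   the Poisson-disk spacing jitter.
#' @param septum_width_base_um Mean endomysial septum width.
#' @param septum_width_jitter_um Standard deviation of per-edge width
#'   jitter (widths are truncated at 0.3 um).
#' @param enhanced_patch Optional `list(center_px = c(x, y),
#'   radius_px, added_width_um)`: septa whose midpoint falls inside the
#'   disk are widened by `added_width_um`, planting a cluster of
#'   enhanced endomysial fibrosis.
#' @param fibrotic_patches List of `list(center_px, radius_px)` disks
#'   rendered as solid WGA-positive fibrosis replacing the cells.
#' @param capillaries_per_myocyte_target Capillaries per myocyte;
#'   capillaries are bright green disks placed at three-cell corners,
#'   inside the WGA-positive septa.
#' @param capillary_area_um2 Mean capillary cross-section area.
#' @param fibroblasts_per_myocyte_target Fibroblasts per myocyte
#'   (blue-channel blobs in the interstitium).
#' @param fibroblast_colocalized_fraction Fraction of additional
#'   fibroblast-channel blobs rendered inside capillaries, emulating
#'   endothelial vimentin cross-reactivity; these are not true
#'   fibroblasts and must vanish under endothelial subtraction.
#' @param noise_sigma Gaussian noise standard deviation added to every
#'   channel (intensity units; membrane contrast is 0.8).
#' @param seed Integer seed; the scene is deterministic per seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_px = c(320L, 320L),
                           resolution_px_per_mm = 2000,
                           n_cells = 100L,
                           mean_cell_diameter_um = 14,
                           septum_width_base_um = 2.5,
                           septum_width_jitter_um = 0.6,
                           enhanced_patch = NULL,
                           fibrotic_patches = list(),
                           capillaries_per_myocyte_target = 0.6,
                           capillary_area_um2 = 15,
                           fibroblasts_per_myocyte_target = 0.5,
                           fibroblast_colocalized_fraction = 0.3,
                           noise_sigma = 0,
                           seed = 1L) {
  spec <- as.list(environment())
  stopifnot(all(spec$image_px >= 64), spec$resolution_px_per_mm > 0,
            spec$n_cells >= 2, spec$mean_cell_diameter_um > 0,
            spec$septum_width_base_um > 0, spec$septum_width_jitter_um >= 0,
            spec$capillaries_per_myocyte_target >= 0,
            spec$fibroblasts_per_myocyte_target >= 0,
            spec$noise_sigma >= 0)
  structure(spec, class = c("synthetic_spec", "list"))
}

#' Generate a synthetic three-channel myocardium micrograph
#'
#' Builds a Voronoi mosaic of myocytes from Poisson-disk seeds, renders
#' bright anti-aliased membranes whose per-edge half-width is half the
#' drawn septum width (so the band between two cells is exactly the
#' edge's septum width wide), solid fibrotic patches, capillaries as
#' green disks at three-cell corners and fibroblasts as irregular blue
#' blobs, then adds Gaussian noise. The returned ground truth is
#' consistent with the rendered scene by construction.
#'
#' Intensity levels: cell interiors 0.1, membranes/fibrosis 0.9 (WGA
#' channel); stained structures 0.9 on a 0.02 background in the colour
#' channels.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_tissue`: calibrated images `wga`,
#'   `endothelial`, `fibroblast`, and `truth`, a list with `cells`
#'   (tibble: `cell_id`, `seed_x_px`, `seed_y_px`, `area_um2`,
#'   `min_feret_um`, `border_flag`), `edges` (tibble: `id_a`, `id_b`,
#'   `width_um`, `in_patch`), `fibrosis_fraction`, `membrane_mask`,
#'   `labels` (Voronoi cell id grid), `capillaries`, `fibroblasts`,
#'   `n_true_fibroblasts` and the spec.
#' @export
generate_tissue <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  nx <- as.integer(spec$image_px[1]); ny <- as.integer(spec$image_px[2])
  upx <- um_per_px(spec$resolution_px_per_mm)

  seeds <- poisson_disk(nx, ny, spec$n_cells,
                        diameter_px = spec$mean_cell_diameter_um / upx)
  n <- nrow(seeds)

  # three nearest seeds per pixel
  px <- as.vector(row(matrix(0, nx, ny))) - 1
  py <- as.vector(col(matrix(0, nx, ny))) - 1
  d1 <- d2 <- d3 <- rep(Inf, nx * ny)
  i1 <- i2 <- i3 <- rep(0L, nx * ny)
  for (i in seq_len(n)) {
    d <- sqrt((px - seeds[i, 1])^2 + (py - seeds[i, 2])^2)
    b3 <- d < d3
    b2 <- d < d2
    b1 <- d < d1
    d3[b3] <- d[b3]; i3[b3] <- i
    d3[b2] <- d2[b2]; i3[b2] <- i2[b2]
    d2[b2] <- d[b2]; i2[b2] <- i
    d2[b1] <- d1[b1]; i2[b1] <- i1[b1]
    d1[b1] <- d[b1]; i1[b1] <- i
  }

  # per-edge septum widths for every pair realised anywhere in the image
  pa <- pmin(i1, i2); pb <- pmax(i1, i2)
  key <- pa * (n + 1) + pb
  ukey <- sort(unique(key))
  ua <- ukey %/% (n + 1); ub <- ukey %% (n + 1)
  widths_um <- pmax(0.3, spec$septum_width_base_um +
                      rnorm(length(ukey), 0, spec$septum_width_jitter_um))
  in_patch <- rep(FALSE, length(ukey))
  if (!is.null(spec$enhanced_patch)) {
    ep <- spec$enhanced_patch
    mx <- (seeds[ua, 1] + seeds[ub, 1]) / 2
    my <- (seeds[ua, 2] + seeds[ub, 2]) / 2
    in_patch <- sqrt((mx - ep$center_px[1])^2 + (my - ep$center_px[2])^2) <= ep$radius_px
    widths_um[in_patch] <- widths_um[in_patch] + ep$added_width_um
  }
  w_px <- widths_um[match(key, ukey)] / upx

  # anti-aliased membrane band of the edge's width around each bisector.
  # The perpendicular distance of a pixel to the bisector line of its
  # two nearest seeds is (d1 + d2)(d2 - d1) / (2 L), L the seed spacing;
  # using it (rather than (d2 - d1)/2, which underestimates the spatial
  # distance away from the seed chord) keeps the band width constant
  # along the whole shared edge.
  L_pair <- sqrt((seeds[i1, 1] - seeds[i2, 1])^2 + (seeds[i1, 2] - seeds[i2, 2])^2)
  sd_bis <- (d1 + d2) * (d2 - d1) / (2 * L_pair)
  f_mem <- pmin(pmax(w_px / 2 - sd_bis + 0.5, 0), 1)
  scene <- 0.1 + 0.8 * f_mem

  # solid fibrotic patches replace cells
  for (fp in spec$fibrotic_patches) {
    dp <- sqrt((px - fp$center_px[1])^2 + (py - fp$center_px[2])^2)
    f_patch <- pmin(pmax(fp$radius_px - dp + 0.5, 0), 1)
    scene <- pmax(scene, 0.1 + 0.8 * f_patch)
  }

  scene <- matrix(scene, nx, ny)
  membrane_mask <- scene >= 0.5
  labels <- matrix(i1, nx, ny)

  # realised adjacency: pairs whose own bisector is approached within
  # 1 px over a substantial stretch (>= 8 such pixels, i.e. a shared
  # boundary of a few pixels). Pairs below that support share only a
  # sliver of boundary engulfed by the corners of wider neighbouring
  # septa; their drawn width is not realised in the scene, so they are
  # not ground-truth edges.
  support <- tapply(sd_bis <= 1, key, sum)
  realised <- as.numeric(names(support)[support >= 8])
  keep <- match(realised, ukey)
  edges <- tibble::tibble(
    id_a = as.integer(ua[keep]), id_b = as.integer(ub[keep]),
    width_um = widths_um[keep], in_patch = in_patch[keep],
    boundary_px = as.integer(support[support >= 8])
  )
  edges <- edges[order(edges$id_a, edges$id_b), ]

  # ground-truth cell measurements on the noise-free mask
  border_ids <- unique(c(labels[1, ], labels[nx, ], labels[, 1], labels[, ny]))
  cellsets <- label_pixel_sets(labels * !membrane_mask)
  cells <- purrr::map_dfr(seq_len(n), function(i) {
    s <- cellsets[[as.character(i)]]
    has <- !is.null(s) && nrow(s) >= 3
    tibble::tibble(
      cell_id = i, seed_x_px = seeds[i, 1], seed_y_px = seeds[i, 2],
      area_um2 = if (has) nrow(s) * upx^2 else 0,
      min_feret_um = if (has)
        suppressWarnings(min_feret(cbind(s$x, s$y), spec$resolution_px_per_mm)) else 0,
      border_flag = i %in% border_ids
    )
  })

  # capillaries at three-cell corners (inside the WGA-positive septa)
  corner_ok <- (d2 - d1) <= 1.2 & (d3 - d2) <= 1.2 &
    px >= 5 & px < nx - 5 & py >= 5 & py < ny - 5
  for (fp in spec$fibrotic_patches) {
    dp <- sqrt((px - fp$center_px[1])^2 + (py - fp$center_px[2])^2)
    corner_ok <- corner_ok & dp > fp$radius_px + 8
  }
  corners <- plateau_centroids(matrix(corner_ok, nx, ny))
  n_cap <- min(round(spec$capillaries_per_myocyte_target * n),
               if (is.null(nrow(corners))) 0 else nrow(corners))
  green <- matrix(0.02, nx, ny)
  caps <- tibble::tibble(x_px = double(), y_px = double(), area_um2 = double(),
                         radius_px = double())
  if (n_cap > 0) {
    pick <- sample.int(nrow(corners), n_cap)
    # enforce a minimal spacing so capillaries never merge
    sel <- integer()
    for (i in pick) {
      if (length(sel) == 0 ||
          all(sqrt((corners[sel, 1] - corners[i, 1])^2 +
                     (corners[sel, 2] - corners[i, 2])^2) > 5 * sqrt(spec$capillary_area_um2 / pi) / upx)) {
        sel <- c(sel, i)
      }
    }
    area <- pmax(3, rnorm(length(sel), spec$capillary_area_um2, spec$capillary_area_um2 / 6))
    r_px <- sqrt(area / pi) / upx
    for (j in seq_along(sel)) {
      dc <- sqrt((px - corners[sel[j], 1])^2 + (py - corners[sel[j], 2])^2)
      green <- pmax(green, matrix(0.02 + 0.88 * pmin(pmax(r_px[j] - dc + 0.5, 0), 1), nx, ny))
    }
    caps <- tibble::tibble(x_px = corners[sel, 1], y_px = corners[sel, 2],
                           area_um2 = area, radius_px = r_px)
  }

  # fibroblasts: irregular blue blobs in the interstitium, plus
  # cross-reactive blobs inside capillaries
  n_fib <- round(spec$fibroblasts_per_myocyte_target * n)
  n_coloc <- min(round(spec$fibroblast_colocalized_fraction * n_fib), nrow(caps))
  blue <- matrix(0.02, nx, ny)
  fib_rows <- list()
  septal <- which(f_mem > 0.9 & px >= 6 & px < nx - 6 & py >= 6 & py < ny - 6)
  if (nrow(caps) > 0 && length(septal) > 0) {
    keep_px <- rep(TRUE, length(septal))
    for (j in seq_len(nrow(caps))) {
      dc <- sqrt((px[septal] - caps$x_px[j])^2 + (py[septal] - caps$y_px[j])^2)
      keep_px <- keep_px & dc > caps$radius_px[j] + 8
    }
    septal <- septal[keep_px]
  }
  placed <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (length(fib_rows) < n_fib && length(septal) > 0 && tries < 50 * n_fib) {
    tries <- tries + 1
    cand <- septal[sample.int(length(septal), 1)]
    cx <- px[cand]; cy <- py[cand]
    if (nrow(placed) > 0 &&
        any(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) < 20)) next
    blue <- render_blob(blue, cx, cy, r_px = 1.8 / upx, irregular = TRUE)
    placed <- rbind(placed, c(cx, cy))
    fib_rows[[length(fib_rows) + 1]] <-
      tibble::tibble(x_px = cx, y_px = cy, colocalized = FALSE)
  }
  if (n_coloc > 0) {
    for (j in seq_len(n_coloc)) {
      blue <- render_blob(blue, caps$x_px[j], caps$y_px[j],
                          r_px = 0.45 * caps$radius_px[j], irregular = FALSE)
      fib_rows[[length(fib_rows) + 1]] <-
        tibble::tibble(x_px = caps$x_px[j], y_px = caps$y_px[j], colocalized = TRUE)
    }
  }
  fibs <- if (length(fib_rows)) dplyr::bind_rows(fib_rows) else
    tibble::tibble(x_px = double(), y_px = double(), colocalized = logical())

  add_noise <- function(m) {
    if (spec$noise_sigma > 0) m <- m + matrix(rnorm(length(m), 0, spec$noise_sigma), nrow(m))
    pmin(pmax(m, 0), 1)
  }
  wga_px <- add_noise(scene)
  endo_px <- array(0.02, c(nx, ny, 3)); endo_px[, , 2] <- green
  endo_px[, , 1] <- add_noise(endo_px[, , 1]); endo_px[, , 2] <- add_noise(endo_px[, , 2])
  endo_px[, , 3] <- add_noise(endo_px[, , 3])
  fib_px <- array(0.02, c(nx, ny, 3)); fib_px[, , 3] <- blue
  fib_px[, , 1] <- add_noise(fib_px[, , 1]); fib_px[, , 2] <- add_noise(fib_px[, , 2])
  fib_px[, , 3] <- add_noise(fib_px[, , 3])

  structure(list(
    wga = calibrated_image(wga_px, spec$resolution_px_per_mm, "wga", "synthetic-wga"),
    endothelial = calibrated_image(endo_px, spec$resolution_px_per_mm, "endothelial",
                                   "synthetic-endothelial"),
    fibroblast = calibrated_image(fib_px, spec$resolution_px_per_mm, "fibroblast",
                                  "synthetic-fibroblast"),
    truth = list(
      cells = cells, edges = edges,
      fibrosis_fraction = mean(membrane_mask),
      membrane_mask = membrane_mask, labels = labels,
      capillaries = caps, fibroblasts = fibs,
      n_true_fibroblasts = sum(!fibs$colocalized),
      spec = spec
    )
  ), class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf(
    "<synthetic_tissue> %d x %d px, %d cells, %d edges, %d capillaries, %d fibroblasts (+%d cross-reactive)\n",
    nrow(x$truth$labels), ncol(x$truth$labels), nrow(x$truth$cells),
    nrow(x$truth$edges), nrow(x$truth$capillaries),
    x$truth$n_true_fibroblasts, sum(x$truth$fibroblasts$colocalized)
  ))
  invisible(x)
}

# dart-throwing Poisson-disk sampling; errors when the density is
# infeasible for the implied minimal spacing (set by the cell count and
# by the nominal cell diameter)
poisson_disk <- function(nx, ny, n_cells, diameter_px = 0, margin = 2) {
  d_min <- max(0.7 * sqrt(nx * ny / n_cells), 0.6 * diameter_px)
  pts <- matrix(numeric(0), ncol = 2)
  attempts <- 0
  while (nrow(pts) < n_cells && attempts < 400 * n_cells) {
    attempts <- attempts + 1
    p <- c(runif(1, margin, nx - 1 - margin), runif(1, margin, ny - 1 - margin))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= d_min) {
      pts <- rbind(pts, p)
    }
  }
  if (nrow(pts) < n_cells) {
    stop("cell density infeasible for the Poisson-disk spacing", call. = FALSE)
  }
  unname(pts)
}

# small anti-aliased blob (optionally a union of jittered disks)
render_blob <- function(m, cx, cy, r_px, irregular = TRUE) {
  nx <- nrow(m); ny <- ncol(m)
  centers <- if (irregular) {
    cbind(cx + runif(3, -r_px / 2, r_px / 2), cy + runif(3, -r_px / 2, r_px / 2))
  } else {
    cbind(cx, cy)
  }
  ro <- ceiling(r_px + 2)
  xs <- max(1, floor(cx - 2 * ro)):min(nx, ceiling(cx + 2 * ro))
  ys <- max(1, floor(cy - 2 * ro)):min(ny, ceiling(cy + 2 * ro))
  sub <- m[xs, ys, drop = FALSE]
  gx <- outer(xs - 1, rep(1, length(ys)))
  gy <- outer(rep(1, length(xs)), ys - 1)
  for (k in seq_len(nrow(centers))) {
    dc <- sqrt((gx - centers[k, 1])^2 + (gy - centers[k, 2])^2)
    sub <- pmax(sub, 0.02 + 0.88 * pmin(pmax(r_px - dc + 0.5, 0), 1))
  }
  m[xs, ys] <- sub
  m
}

#' Ground-truth CDI from true septum widths
#'
#' Applies the cardiomyocyte dissociation index definition to the
#' generator's true edge widths, for pipeline-recovery comparisons.
#'
#' @param truth The `truth` element of a [generate_tissue()] result (or
#'   the whole `synthetic_tissue`).
#' @param ref A [reference_stats()].
#' @return A tibble `cell_id`, `n_neighbors`, `n_enhanced`, `cdi`.
#' @export
ground_truth_cdi <- function(truth, ref) {
  if (inherits(truth, "synthetic_tissue")) truth <- truth$truth
  thr <- enhancement_threshold(ref)
  ids <- truth$cells$cell_id
  edges <- truth$edges
  enhanced <- edges$width_um > thr
  deg <- enh <- setNames(integer(length(ids)), ids)
  for (col in c("id_a", "id_b")) {
    deg <- deg + as.integer(table(factor(edges[[col]], levels = ids)))
    enh <- enh + as.integer(table(factor(edges[[col]][enhanced], levels = ids)))
  }
  tibble::tibble(
    cell_id = ids, n_neighbors = as.integer(deg), n_enhanced = as.integer(enh),
    cdi = unname(ifelse(deg > 0, enh / deg, NA_real_))
  )
}
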