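#' Segment cardiomyocytes in a thresholded WGA image
#'
#' Detects individual transversely cut cardiomyocytes as basins of the
#' blurred WGA intensity and delineates them by seeded Voronoi
#' watershedding:
#'
#' 1. the intensity plane is Gaussian-blurred to suppress noise;
#' 2. the detection prominence is set from the image itself as
#'    `contrast_scale * (mean intensity over WGA-positive pixels - mean
#'    over WGA-negative pixels)`;
#' 3. local minima of the blurred plane with dynamic (prominence) at
#'    least that value are kept as candidate cell seeds, found as the
#'    regional minima of the h-minima transform (morphological
#'    reconstruction by erosion of `f + h` over `f`); plateaus are
#'    merged to their centroid;
#' 4. candidates whose surrounding annulus is predominantly
#'    WGA-positive are rejected: they are dim pockets inside fibrotic
#'    patches, not cells (the red-surround rule);
#' 5. a Voronoi watershed grown from the surviving seeds over the
#'    blurred intensity partitions the image; each region clipped to the
#'    WGA-negative space is one myocyte, measured by area and minimal
#'    Feret diameter.
#'
#' Regions touching the image border or smaller than
#' `min_cell_area_um2` are flagged (`size_ok = FALSE`) and excluded from
#' size statistics, but remain nodes of the neighbour graph.
#'
#' @param image A WGA [calibrated_image()].
#' @param mask Logical matrix from [phansalkar_threshold()] on `image`.
#' @param config An [analysis_config()].
#'
#' @return An object of class `myocyte_seg`: list with `records` (a
#'   tibble, one row per myocyte: `myocyte_id`, `seed_x_px`,
#'   `seed_y_px`, `centroid_x_px`, `centroid_y_px`, `area_um2`,
#'   `min_feret_um`, `border_flag`, `size_ok`), `labels` (integer
#'   watershed label grid) and `prominence`.
#' @export
detect_myocytes <- function(image, mask, config = analysis_config()) {
  stopifnot(inherits(image, "calibrated_image"))
  plane <- intensity_plane(image)
  stopifnot(identical(dim(plane), dim(mask)))
  upx <- pixel_size_um(image)

  fg <- plane[mask]
  bg <- plane[!mask]
  if (length(fg) == 0 || length(bg) == 0) {
    stop("degenerate threshold: mask is all-positive or all-negative", call. = FALSE)
  }
  prominence <- config$contrast_scale * (mean(fg) - mean(bg))
  if (!is.finite(prominence) || prominence <= 0) {
    stop("degenerate contrast: non-positive detection prominence", call. = FALSE)
  }

  blurred <- matrix(EBImage::gblur(plane, sigma = config$blur_sigma_px),
                    nrow(plane), ncol(plane))

  hm <- hmin_transform(blurred, prominence)
  cand <- (hm <= window_filter(hm, 1L, pmin) + 1e-12) & !mask

  seeds_xy <- plateau_centroids(cand)
  if (nrow(seeds_xy) > 0) {
    keep <- !red_surround(seeds_xy, mask,
                          config$surround_r_inner_px, config$surround_r_outer_px,
                          config$surround_max_fraction)
    seeds_xy <- seeds_xy[keep, , drop = FALSE]
  }

  empty <- tibble::tibble(
    myocyte_id = integer(), seed_x_px = double(), seed_y_px = double(),
    centroid_x_px = double(), centroid_y_px = double(),
    area_um2 = double(), min_feret_um = double(),
    border_flag = logical(), size_ok = logical()
  )
  if (nrow(seeds_xy) == 0) {
    return(structure(list(records = empty,
                          labels = matrix(0L, nrow(plane), ncol(plane)),
                          prominence = prominence, image = image, mask = mask),
                     class = "myocyte_seg"))
  }

  seed_grid <- matrix(0L, nrow(plane), ncol(plane))
  sx <- pmin(pmax(round(seeds_xy[, 1]), 0), nrow(plane) - 1) + 1
  sy <- pmin(pmax(round(seeds_xy[, 2]), 0), ncol(plane) - 1) + 1
  # first seed wins if two plateau centroids round to the same pixel
  dup <- duplicated(cbind(sx, sy))
  sx <- sx[!dup]; sy <- sy[!dup]
  seeds_xy <- seeds_xy[!dup, , drop = FALSE]
  seed_grid[cbind(sx, sy)] <- seq_along(sx)

  labels <- EBImage::propagate(blurred, seed_grid)
  labels <- matrix(as.integer(labels), nrow(plane), ncol(plane))

  nx <- nrow(labels); ny <- ncol(labels)
  border_ids <- unique(c(labels[1, ], labels[nx, ], labels[, 1], labels[, ny]))

  records <- purrr::map_dfr(seq_along(sx), function(id) {
    in_region <- labels == id
    cellpx <- which(in_region & !mask)
    n_cell <- length(cellpx)
    if (n_cell > 0) {
      cx <- (cellpx - 1) %% nx
      cy <- (cellpx - 1) %/% nx
      centroid <- c(mean(cx), mean(cy))
      feret <- suppressWarnings(min_feret(cbind(cx, cy), image$resolution_px_per_mm))
    } else {
      centroid <- c(sx[id] - 1, sy[id] - 1)
      feret <- 0
    }
    area <- n_cell * upx^2
    tibble::tibble(
      myocyte_id = id,
      seed_x_px = sx[id] - 1, seed_y_px = sy[id] - 1,
      centroid_x_px = centroid[1], centroid_y_px = centroid[2],
      area_um2 = area, min_feret_um = feret,
      border_flag = id %in% border_ids,
      size_ok = !(id %in% border_ids) && area >= config$min_cell_area_um2
    )
  })
  if (nrow(records) == 0) records <- empty

  structure(list(records = records, labels = labels, prominence = prominence,
                 image = image, mask = mask),
            class = "myocyte_seg")
}

#' @export
print.myocyte_seg <- function(x, ...) {
  cat(sprintf("<myocyte_seg> %d myocytes (%d in size statistics), prominence %.4g\n",
              nrow(x$records), sum(x$records$size_ok), x$prominence))
  invisible(x)
}

#' @export
tidy.myocyte_seg <- function(x, ...) x$records

# h-minima transform: morphological reconstruction by erosion of
# (f + h) over f; its regional minima are exactly the minima of f with
# dynamic (prominence) >= h
hmin_transform <- function(f, h, max_iter = 2000L) {
  rec <- f + h
  for (i in seq_len(max_iter)) {
    new <- pmax(f, window_filter(rec, 1L, pmin))
    if (max(abs(new - rec)) < 1e-10) return(new)
    rec <- new
  }
  rec
}

# connected plateaus of candidate minima -> one centroid each (0-based x, y)
plateau_centroids <- function(cand) {
  lab <- label_components(cand, connectivity = 8)
  sets <- label_pixel_sets(lab)
  if (length(sets) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, lapply(sets, function(s) c(mean(s$x), mean(s$y))))
}

# TRUE where the annulus around a seed is predominantly mask-positive
red_surround <- function(seeds_xy, mask, r_inner, r_outer, max_fraction) {
  ro <- ceiling(r_outer)
  off <- expand.grid(dx = -ro:ro, dy = -ro:ro)
  d2 <- off$dx^2 + off$dy^2
  off <- off[d2 > r_inner^2 & d2 <= r_outer^2, ]
  nx <- nrow(mask); ny <- ncol(mask)
  vapply(seq_len(nrow(seeds_xy)), function(i) {
    xs <- round(seeds_xy[i, 1]) + off$dx
    ys <- round(seeds_xy[i, 2]) + off$dy
    ok <- xs >= 0 & xs < nx & ys >= 0 & ys < ny
    if (!any(ok)) return(FALSE)
    mean(mask[cbind(xs[ok] + 1, ys[ok] + 1)]) > max_fraction
  }, logical(1))
}
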