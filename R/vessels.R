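#' Hue-Saturation-Brightness colour threshold
#'
#' Selects stain-positive pixels of an RGB channel image by colour: a
#' Gaussian blur is applied, the image is converted to HSB, and a pixel
#' is positive when its hue lies in the given (circular) interval and
#' saturation and brightness reach their floors. This is the standard
#' HSB colour-threshold approach for counting fluorescent structures.
#'
#' @param image An RGB [calibrated_image()].
#' @param hue_range_deg Length-2 hue interval in degrees `[0, 360)`;
#'   wrap-around intervals (e.g. `c(330, 30)`) are allowed.
#' @param sat_min,bright_min Saturation and brightness floors in `[0, 1]`.
#' @param blur_sigma_px Gaussian blur sigma (0 disables).
#' @return A logical mask of the image dimensions.
#' @export
hsb_threshold <- function(image, hue_range_deg = c(80, 160),
                          sat_min = 0.15, bright_min = 0.15,
                          blur_sigma_px = 2) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  if (length(dim(px)) != 3) {
    stop("HSB thresholding requires an RGB image (grayscale input given)", call. = FALSE)
  }
  if (blur_sigma_px > 0) {
    for (ch in 1:3) px[, , ch] <- matrix(EBImage::gblur(px[, , ch], sigma = blur_sigma_px),
                                         dim(px)[1], dim(px)[2])
    px <- pmin(pmax(px, 0), 1)  # gblur ringing can leave [0,1] slightly
  }
  hsv <- grDevices::rgb2hsv(
    r = as.vector(px[, , 1]), g = as.vector(px[, , 2]), b = as.vector(px[, , 3]),
    maxColorValue = 1
  )
  hue <- hsv[1, ] * 360
  lo <- hue_range_deg[1] %% 360
  hi <- hue_range_deg[2] %% 360
  in_hue <- if (lo <= hi) hue >= lo & hue <= hi else hue >= lo | hue <= hi
  keep <- in_hue & hsv[2, ] >= sat_min & hsv[3, ] >= bright_min
  matrix(keep, dim(px)[1], dim(px)[2])
}

# outer-boundary chain length of one labelled component with the
# Vossepoel-Smeulders corner-corrected weights (0.980 per axis step,
# 1.406 per diagonal step, -0.091 per direction change): unlike the
# plain sqrt(2)-weighted chain, this estimate is asymptotically
# unbiased for smooth shapes, so digitised disk circularity converges
# to 1 with radius; single-pixel components get the perimeter of a
# square
chain_perimeter <- function(component_mask) {
  if (sum(component_mask) == 1) return(4)
  oc <- EBImage::ocontour(matrix(as.numeric(component_mask),
                                 nrow(component_mask), ncol(component_mask)))[[1]]
  steps <- rbind(diff(oc), oc[1, , drop = FALSE] - oc[nrow(oc), , drop = FALSE])
  diag_step <- abs(steps[, 1]) + abs(steps[, 2]) == 2
  turns <- sum(steps[, 1] != c(steps[-1, 1], steps[1, 1]) |
                 steps[, 2] != c(steps[-1, 2], steps[1, 2]))
  max(1, 0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * turns)
}

#' Detect capillaries in a thresholded endothelial image
#'
#' Particle analysis of the endothelial (CD31 / GS-IB4) mask:
#' 8-connected components smaller than `min_area_um2` are discarded as
#' noise; every surviving component counts towards the capillary count.
#' Components with circularity (`4 pi area / perimeter^2`) at or above
#' `circ_gate` are classified as transversely cut and additionally
#' sized by their minimal Feret diameter; non-circular (obliquely or
#' longitudinally cut) objects are counted but not sized.
#'
#' @param mask Logical mask from [hsb_threshold()].
#' @param resolution_px_per_mm Spatial calibration.
#' @param min_area_um2 Minimal component area (um^2).
#' @param circ_gate Circularity gate selecting transverse sections.
#' @return A tibble with one row per capillary: `capillary_id`,
#'   `centroid_x_px`, `centroid_y_px`, `area_um2`, `circularity`,
#'   `transverse`, `min_feret_um` (`NA` unless transverse).
#' @export
detect_capillaries <- function(mask, resolution_px_per_mm,
                               min_area_um2 = 1.5, circ_gate = 0.35) {
  upx <- um_per_px(resolution_px_per_mm)
  lab <- label_components(mask, connectivity = 8)
  sets <- label_pixel_sets(lab)
  out <- purrr::map_dfr(seq_along(sets), function(i) {
    s <- sets[[i]]
    area_um2 <- nrow(s) * upx^2
    if (area_um2 < min_area_um2) return(NULL)
    comp <- matrix(FALSE, nrow(mask), ncol(mask))
    comp[cbind(s$x + 1, s$y + 1)] <- TRUE
    per_px <- chain_perimeter(comp)
    circ <- min(1, 4 * pi * nrow(s) / per_px^2)
    transverse <- circ >= circ_gate
    tibble::tibble(
      centroid_x_px = mean(s$x), centroid_y_px = mean(s$y),
      area_um2 = area_um2, circularity = circ, transverse = transverse,
      min_feret_um = if (transverse) {
        suppressWarnings(min_feret(cbind(s$x, s$y), resolution_px_per_mm))
      } else NA_real_
    )
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(capillary_id = integer(), centroid_x_px = double(),
                          centroid_y_px = double(), area_um2 = double(),
                          circularity = double(), transverse = logical(),
                          min_feret_um = double()))
  }
  dplyr::bind_cols(tibble::tibble(capillary_id = seq_len(nrow(out))), out)
}

#' Count fibroblasts after endothelial subtraction
#'
#' Vimentin cross-reacts with endothelial cells, so the thresholded
#' endothelial mask is subtracted pixel-wise from the thresholded
#' vimentin mask before counting: a fibroblast is an 8-connected
#' component of `vimentin AND NOT endothelial` at least
#' `min_area_um2` large. A component reduced below the size gate by the
#' subtraction is dropped entirely.
#'
#' @param vimentin_mask,endothelial_mask Logical masks of equal shape
#'   (from [hsb_threshold()] of the respective channels).
#' @param resolution_px_per_mm Spatial calibration.
#' @param min_area_um2 Minimal fibroblast component area (um^2).
#' @return A tibble with one row per fibroblast: `fibroblast_id`,
#'   `centroid_x_px`, `centroid_y_px`, `area_um2`.
#' @export
fibroblast_count <- function(vimentin_mask, endothelial_mask,
                             resolution_px_per_mm, min_area_um2 = 1.5) {
  if (!identical(dim(vimentin_mask), dim(endothelial_mask))) {
    stop("vimentin and endothelial masks have different shapes", call. = FALSE)
  }
  upx <- um_per_px(resolution_px_per_mm)
  residual <- vimentin_mask & !endothelial_mask
  lab <- label_components(residual, connectivity = 8)
  sets <- label_pixel_sets(lab)
  out <- purrr::map_dfr(seq_along(sets), function(i) {
    s <- sets[[i]]
    area_um2 <- nrow(s) * upx^2
    if (area_um2 < min_area_um2) return(NULL)
    tibble::tibble(centroid_x_px = mean(s$x), centroid_y_px = mean(s$y),
                   area_um2 = area_um2)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(fibroblast_id = integer(), centroid_x_px = double(),
                          centroid_y_px = double(), area_um2 = double()))
  }
  dplyr::bind_cols(tibble::tibble(fibroblast_id = seq_len(nrow(out))), out)
}

#' Per-myocyte capillary and fibroblast densities
#'
#' Capillary density is the number of capillaries per myocyte (a count
#' ratio robust to hypertrophy, unlike per-area density); fibroblast
#' density likewise. Per-area capillary density (count per mm^2) is
#' also reported when the image area is supplied.
#'
#' @param capillaries Tibble from [detect_capillaries()] (or a count).
#' @param fibroblasts Tibble from [fibroblast_count()] (or a count).
#' @param myocyte_count Number of myocytes in the paired WGA image.
#' @param image_area_mm2 Optional analysed area in mm^2.
#' @return A one-row tibble: `capillary_count`,
#'   `capillaries_per_myocyte`, `fibroblast_count`,
#'   `fibroblasts_per_myocyte`, `capillaries_per_mm2`. Per-myocyte
#'   ratios are `NA` (undefined) when `myocyte_count` is 0.
#' @export
densities <- function(capillaries, fibroblasts, myocyte_count, image_area_mm2 = NA_real_) {
  ncap <- if (is.data.frame(capillaries)) nrow(capillaries) else as.integer(capillaries)
  nfib <- if (is.data.frame(fibroblasts)) nrow(fibroblasts) else as.integer(fibroblasts)
  ratio <- function(num) if (myocyte_count > 0) num / myocyte_count else NA_real_
  tibble::tibble(
    capillary_count = ncap,
    capillaries_per_myocyte = ratio(ncap),
    fibroblast_count = nfib,
    fibroblasts_per_myocyte = ratio(nfib),
    capillaries_per_mm2 = if (is.finite(image_area_mm2) && image_area_mm2 > 0)
      ncap / image_area_mm2 else NA_real_
  )
}
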