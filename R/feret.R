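#' Minimal Feret diameter of a pixel region or polygon
#'
#' The minimal width of the region over all projection directions
#' (smallest caliper distance), the size measure used for myocytes and
#' transversely cut capillaries: under approximately transverse
#' sectioning it underestimates true cross-sections only slightly and
#' systematically, unlike the maximal width.
#'
#' Computed exactly on the convex hull: the minimal width of a convex
#' polygon is attained perpendicular to one of its edges, so the result
#' is the minimum over hull edges of the farthest vertex distance to the
#' edge line. Pixel regions are measured on pixel corners (each pixel
#' contributes its four corner points), so an axis-aligned w-pixel-wide
#' bar measures exactly w pixels.
#'
#' @param coords Two-column matrix (or data frame) of `(x, y)`
#'   coordinates: 0-based pixel centres when `pixel_centers = TRUE`,
#'   arbitrary polygon vertices otherwise.
#' @param resolution_px_per_mm Optional calibration; when supplied the
#'   result is in micrometres, otherwise in pixels.
#' @param pixel_centers Treat rows as pixel centres and measure on the
#'   pixel corner cloud.
#' @return Minimal Feret diameter (um, or px when uncalibrated);
#'   degenerate (collinear) regions return 0 with a warning.
#' @export
min_feret <- function(coords, resolution_px_per_mm = NULL, pixel_centers = TRUE) {
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(xy) <- "double"
  if (pixel_centers) {
    xy <- rbind(
      cbind(xy[, 1] - 0.5, xy[, 2] - 0.5), cbind(xy[, 1] + 0.5, xy[, 2] - 0.5),
      cbind(xy[, 1] - 0.5, xy[, 2] + 0.5), cbind(xy[, 1] + 0.5, xy[, 2] + 0.5)
    )
  }
  xy <- unique(xy)
  scale <- if (is.null(resolution_px_per_mm)) 1 else um_per_px(resolution_px_per_mm)
  if (nrow(xy) < 3) {
    warning("degenerate region: fewer than 3 distinct points")
    return(0)
  }
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 3) {
    warning("degenerate (collinear) region")
    return(0)
  }
  widths <- vapply(seq_len(nh), function(i) {
    a <- hull[i, ]
    b <- hull[if (i == nh) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    max(abs((xy[, 1] - a[1]) * e[2] - (xy[, 2] - a[2]) * e[1])) / len
  }, numeric(1))
  w <- min(widths)
  if (!is.finite(w) || w == 0) {
    warning("degenerate (collinear) region")
    return(0)
  }
  w * scale
}

# minimal width plus its direction (unit normal of the best hull edge),
# used to draw the Feret segment on control overlays
min_feret_info <- function(coords) {
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(xy) <- "double"
  xy <- rbind(
    cbind(xy[, 1] - 0.5, xy[, 2] - 0.5), cbind(xy[, 1] + 0.5, xy[, 2] - 0.5),
    cbind(xy[, 1] - 0.5, xy[, 2] + 0.5), cbind(xy[, 1] + 0.5, xy[, 2] + 0.5)
  )
  xy <- unique(xy)
  if (nrow(xy) < 3) return(NULL)
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 3) return(NULL)
  best <- NULL
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) next
    w <- max(abs((xy[, 1] - a[1]) * e[2] - (xy[, 2] - a[2]) * e[1])) / len
    if (is.null(best) || w < best$width_px) {
      best <- list(width_px = w, normal = c(-e[2], e[1]) / len)
    }
  }
  best
}
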