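#' Phansalkar local adaptive threshold
#'
#' Delineates stain-positive pixels in low-contrast fluorescence images.
#' A pixel is positive when its intensity exceeds the local threshold
#' `t = m (1 + p e^(-q m) + k (s/r - 1))`, where `m` and `s` are the mean
#' and (population) standard deviation over a disk of radius
#' `radius_px` centred on the pixel; the image boundary is handled by
#' mirror padding. For RGB WGA images the red plane is thresholded.
#'
#' @param image A [calibrated_image()] (or a plain numeric matrix in
#'   `[0, 1]`).
#' @param radius_px Disk radius in pixels.
#' @param k,r,p,q Phansalkar constants.
#' @param config Optional [analysis_config()] supplying the parameters
#'   (overridden by the explicit arguments).
#'
#' @return A logical matrix of the image dimensions, `TRUE` = stain
#'   positive, with attribute `method` describing the threshold.
#' @export
phansalkar_threshold <- function(image, radius_px = NULL, k = NULL, r = NULL,
                                 p = NULL, q = NULL, config = analysis_config()) {
  radius_px <- radius_px %||% config$phansalkar_radius_px
  k <- k %||% config$phansalkar_k
  r <- r %||% config$phansalkar_r
  p <- p %||% config$phansalkar_p
  q <- q %||% config$phansalkar_q
  m <- if (inherits(image, "calibrated_image")) intensity_plane(image) else image
  stopifnot(is.matrix(m), radius_px >= 1, r > 0)
  if (2 * radius_px > min(dim(m))) {
    stop("Phansalkar radius exceeds half the image side", call. = FALSE)
  }
  mu <- disk_mean(m, radius_px)
  m2 <- disk_mean(m * m, radius_px)
  s <- sqrt(pmax(m2 - mu^2, 0))
  t <- mu * (1 + p * exp(-q * mu) + k * (s / r - 1))
  mask <- m > t
  attr(mask, "method") <- sprintf(
    "phansalkar(radius=%d, k=%g, r=%g, p=%g, q=%g)", as.integer(radius_px), k, r, p, q
  )
  mask
}

#' Fibrosis fraction of a thresholded WGA image
#'
#' Fraction of WGA-positive pixels over the total pixel count, the
#' overall (endomysial plus perimysial) fibrosis measure of the image.
#'
#' @param mask Logical matrix from [phansalkar_threshold()].
#' @return A number in `[0, 1]`.
#' @export
fibrosis_fraction <- function(mask) {
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  mean(mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
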