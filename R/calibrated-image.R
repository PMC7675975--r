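#' Calibrated micrograph
#'
#' Container pairing raw pixel data with a spatial calibration and the
#' channel it represents. All downstream measurements are reported in
#' micrometres using `1000 / resolution_px_per_mm` micrometres per pixel
#' (square pixels are assumed).
#'
#' @param pixels Numeric matrix (grayscale) or 3-d array with a third
#'   dimension of 3 (RGB), values in `[0, 1]`. First dimension is x
#'   (column), second y (row), origin top-left.
#' @param resolution_px_per_mm Positive number of pixels per millimetre.
#' @param channel_role One of `"wga"` (membrane/extracellular matrix),
#'   `"endothelial"` (CD31 / GS-IB4) or `"fibroblast"` (vimentin).
#' @param source_id Identifier (typically the file path) carried into
#'   output tables.
#'
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, resolution_px_per_mm,
                             channel_role = c("wga", "endothelial", "fibroblast"),
                             source_id = "image") {
  channel_role <- match.arg(channel_role)
  if (!is.numeric(resolution_px_per_mm) || length(resolution_px_per_mm) != 1 ||
      !is.finite(resolution_px_per_mm) || resolution_px_per_mm <= 0) {
    stop("`resolution_px_per_mm` must be a single positive number", call. = FALSE)
  }
  d <- dim(pixels)
  if (!(length(d) == 2 || (length(d) == 3 && d[3] == 3))) {
    stop("`pixels` must be a 2-d matrix or an x-by-y-by-3 RGB array", call. = FALSE)
  }
  if (d[1] < 64 || d[2] < 64) {
    stop("image must be at least 64 x 64 pixels", call. = FALSE)
  }
  if (any(pixels < 0, na.rm = TRUE)) stop("pixel values must be non-negative", call. = FALSE)
  structure(
    list(
      pixels = pixels,
      resolution_px_per_mm = resolution_px_per_mm,
      channel_role = channel_role,
      source_id = source_id
    ),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<calibrated_image> %s  %d x %d px%s  %.4g um/px  [%s]\n",
    x$channel_role, d[1], d[2], if (length(d) == 3) " (RGB)" else "",
    um_per_px(x$resolution_px_per_mm), x$source_id
  ))
  invisible(x)
}

#' Micrometres per pixel of a calibrated image
#' @param image A [calibrated_image()].
#' @return Pixel side length in micrometres.
#' @export
pixel_size_um <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  um_per_px(image$resolution_px_per_mm)
}

# single intensity plane used for thresholding/segmentation:
# the red plane of an RGB WGA image, the grayscale plane otherwise
intensity_plane <- function(image, plane = NULL) {
  px <- image$pixels
  if (length(dim(px)) == 2) return(px)
  if (is.null(plane)) {
    plane <- switch(image$channel_role, wga = 1L, endothelial = 2L, fibroblast = 3L)
  }
  px[, , plane]
}

#' Load one channel image with its spatial calibration
#'
#' Reads a TIFF, PNG, JPEG or uncompressed BMP micrograph and attaches the
#' pixels-per-millimetre calibration and channel role. Intensities are
#' min-max normalised to `[0, 1]` per image (constant images are scaled by
#' their bit depth instead), so that one threshold parameter set serves
#' both 8-bit and 16-bit acquisitions. RGB images retain all three planes;
#' the WGA analysis extracts the red plane itself.
#'
#' @inheritParams calibrated_image
#' @param path Path to the image file.
#' @return A [calibrated_image()].
#' @export
load_channel <- function(path, resolution_px_per_mm,
                         channel_role = c("wga", "endothelial", "fibroblast")) {
  channel_role <- match.arg(channel_role)
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  if (!is.numeric(resolution_px_per_mm) || resolution_px_per_mm <= 0) {
    stop("`resolution_px_per_mm` must be positive", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(
    ext,
    tif = ,
    tiff = read_tiff_raw(path),
    bmp = read_bmp_raw(path),
    {
      img <- EBImage::readImage(path)
      list(values = unclass(EBImage::imageData(img)), max_value = 1)
    }
  )
  px <- raw$values
  d <- dim(px)
  if (length(d) == 3 && d[3] > 3) px <- px[, , 1:3]
  rng <- range(px)
  if (rng[2] > rng[1]) {
    px <- (px - rng[1]) / (rng[2] - rng[1])
  } else if (raw$max_value > 1) {
    px <- px / raw$max_value
  }
  calibrated_image(px, resolution_px_per_mm, channel_role, source_id = path)
}

# TIFF reader preserving native integer range so 8- vs 16-bit depth is known
read_tiff_raw <- function(path) {
  v <- tiff::readTIFF(path, as.is = TRUE)
  maxv <- if (max(v) > 255) 65535 else 255
  list(values = transpose_raster(v), max_value = maxv)
}

# tiff/png readers return [row, col(, channel)]; convert to [x, y(, channel)]
transpose_raster <- function(v) {
  if (length(dim(v)) == 2) return(t(v))
  aperm(v, c(2, 1, 3))
}

# minimal reader for uncompressed 24-bit / 8-bit-palette-free BMP files
read_bmp_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 2)
  if (!identical(rawToChar(sig), "BM")) stop("not a BMP file: ", path, call. = FALSE)
  readBin(con, "integer", 2, size = 4, endian = "little")   # file size + reserved
  offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  w <- readBin(con, "integer", 1, size = 4, endian = "little")
  h <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")   # planes
  bpp <- readBin(con, "integer", 1, size = 2, endian = "little")
  comp <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (comp != 0 || !(bpp %in% c(8, 24))) {
    stop("only uncompressed 8-bit or 24-bit BMP is supported: ", path, call. = FALSE)
  }
  seek(con, offset)
  row_bytes <- ((bpp / 8 * w + 3) %/% 4) * 4
  data <- readBin(con, "raw", row_bytes * abs(h))
  top_down <- h < 0
  h <- abs(h)
  rows <- matrix(as.integer(data), nrow = row_bytes)[seq_len(bpp / 8 * w), , drop = FALSE]
  if (bpp == 8) {
    m <- rows  # w x h, rows bottom-up unless top_down
    vals <- m
    arr <- matrix(vals, nrow = w, ncol = h)
    if (!top_down) arr <- arr[, h:1, drop = FALSE]
    list(values = arr, max_value = 255)
  } else {
    b <- rows[seq(1, 3 * w, by = 3), , drop = FALSE]
    g <- rows[seq(2, 3 * w, by = 3), , drop = FALSE]
    r <- rows[seq(3, 3 * w, by = 3), , drop = FALSE]
    flip <- function(m) if (!top_down) m[, h:1, drop = FALSE] else m
    arr <- array(0, c(w, h, 3))
    arr[, , 1] <- flip(r); arr[, , 2] <- flip(g); arr[, , 3] <- flip(b)
    list(values = arr, max_value = 255)
  }
}

#' Write a calibrated image (or plain pixel grid) to disk
#'
#' Convenience wrapper used by the synthetic-tissue generator and the
#' overlay writer; TIFF output preserves the `[0, 1]` scale at the
#' requested bit depth.
#'
#' @param image A [calibrated_image()] or a numeric matrix/array in `[0, 1]`.
#' @param path Output path; format chosen by extension (`.tif`, `.png`).
#' @param bits_per_sample 8 or 16 (TIFF only).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path, bits_per_sample = 8) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  px <- pmin(pmax(px, 0), 1)
  v <- if (length(dim(px)) == 2) t(px) else aperm(px, c(2, 1, 3))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, path, bits.per.sample = bits_per_sample)
  } else if (ext == "png") {
    png::writePNG(v, path)
  } else {
    stop("unsupported output format: ", ext, call. = FALSE)
  }
  invisible(path)
}
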