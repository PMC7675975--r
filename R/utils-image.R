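# Internal raster helpers.
#
# Pixel grids are numeric matrices indexed [x + 1, y + 1] (EBImage layout:
# first dimension horizontal). Reported coordinates are 0-based pixel-centre
# indices, origin top-left, x = column, y = row.

# micrometres per pixel for a given calibration
um_per_px <- function(resolution_px_per_mm) 1000 / resolution_px_per_mm

# shift a matrix by (dx, dy) with edge replication
shift_mat <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- pmin(pmax(seq_len(nx) - dx, 1L), nx)
  iy <- pmin(pmax(seq_len(ny) - dy, 1L), ny)
  m[ix, iy, drop = FALSE]
}

# separable square-window running min/max of radius r (window side 2r + 1)
window_filter <- function(m, r, fun = pmin) {
  out <- m
  for (i in seq_len(r)) {
    out <- fun(out, shift_mat(out, 1L, 0L), shift_mat(out, -1L, 0L))
  }
  for (i in seq_len(r)) {
    out <- fun(out, shift_mat(out, 0L, 1L), shift_mat(out, 0L, -1L))
  }
  out
}

# symmetric (half-sample mirror) padding by r pixels on each side
mirror_pad <- function(m, r) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- c(rev(seq_len(min(r, nx))), seq_len(nx), nx + 1 - seq_len(min(r, nx)))
  iy <- c(rev(seq_len(min(r, ny))), seq_len(ny), ny + 1 - seq_len(min(r, ny)))
  m[ix, iy, drop = FALSE]
}

# binary disk kernel of pixel radius r (matrix of 0/1, odd side)
disk_kernel <- function(r) {
  d <- 2L * r + 1L
  off <- seq_len(d) - r - 1L
  k <- outer(off^2, off^2, `+`) <= r^2
  storage.mode(k) <- "double"
  k
}

# local mean over a disk neighbourhood with mirror-padded boundary
disk_mean <- function(m, r) {
  k <- disk_kernel(r)
  k <- k / sum(k)
  p <- mirror_pad(m, r)
  f <- EBImage::filter2(p, k, boundary = "circular")
  f[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

# bilinear interpolation at continuous 0-based coordinates (x, y)
bilinear_sample <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), ny - 2); y1 <- y0 + 1
  if (nx == 1) { x0 <- x1 <- 0 }
  if (ny == 1) { y0 <- y1 <- 0 }
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0 + 1, y0 + 1); i10 <- cbind(x1 + 1, y0 + 1)
  i01 <- cbind(x0 + 1, y1 + 1); i11 <- cbind(x1 + 1, y1 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i10] * fx * (1 - fy) +
    m[i01] * (1 - fx) * fy + m[i11] * fx * fy
}

# nearest-neighbour sample of an integer label grid
nearest_sample <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  xi <- pmin(pmax(round(x), 0), nx - 1) + 1
  yi <- pmin(pmax(round(y), 0), ny - 1) + 1
  m[cbind(xi, yi)]
}

# 8-connected component labelling: 4-connected bwlabel, then merge labels
# that touch diagonally (union-find over the label set)
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (connectivity == 4 || nl <= 1) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), -ncol(lab)]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -ncol(lab)]), as.vector(lab[-nrow(lab), -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# per-label pixel index lists; returns list of 2-col matrices of 0-based (x, y)
label_pixel_sets <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) return(list())
  xs <- (idx - 1) %% nrow(lab)
  ys <- (idx - 1) %/% nrow(lab)
  split(data.frame(x = xs, y = ys), lab[idx])
}

# draw a line segment into a matrix (used by overlays); coords 0-based
draw_segment <- function(m, x0, y0, x1, y1, value) {
  len <- max(abs(x1 - x0), abs(y1 - y0), 1)
  t <- seq(0, 1, length.out = ceiling(len) * 2 + 1)
  xi <- pmin(pmax(round(x0 + t * (x1 - x0)), 0), nrow(m) - 1) + 1
  yi <- pmin(pmax(round(y0 + t * (y1 - y0)), 0), ncol(m) - 1) + 1
  m[cbind(xi, yi)] <- value
  m
}
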