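# Independent brute-force oracles and small fixture builders used across
# the test files. Oracles deliberately avoid the implementation paths
# they check.

# --- rotation-scan minimal width: min over a fine angle grid of the
# projected extent of the point cloud (pixel corners when requested)
oracle_min_feret <- function(xy, pixel_centers = TRUE, step_deg = 0.25) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  if (pixel_centers) {
    xy <- rbind(
      cbind(xy[, 1] - 0.5, xy[, 2] - 0.5), cbind(xy[, 1] + 0.5, xy[, 2] - 0.5),
      cbind(xy[, 1] - 0.5, xy[, 2] + 0.5), cbind(xy[, 1] + 0.5, xy[, 2] + 0.5)
    )
  }
  angles <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(angles, function(a) {
    p <- xy[, 1] * cos(a) + xy[, 2] * sin(a)
    max(p) - min(p)
  }, numeric(1))
  min(widths)
}

# --- exhaustive triangle-count average clustering on a small graph
oracle_average_clustering <- function(edge_matrix, n) {
  A <- matrix(FALSE, n, n)
  if (nrow(edge_matrix)) {
    A[edge_matrix] <- TRUE
    A[edge_matrix[, 2:1, drop = FALSE]] <- TRUE
  }
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ])
    d <- length(nb)
    if (d < 2) next
    tri <- 0
    for (i in seq_len(d - 1)) for (j in (i + 1):d) {
      if (A[nb[i], nb[j]]) tri <- tri + 1
    }
    cc[v] <- 2 * tri / (d * (d - 1))
  }
  mean(cc)
}

# --- exhaustive minimum-total-distance one-to-one assignment
# (manual side must be small); returns matrix of (manual, auto) pairs
oracle_assignment <- function(manual, auto, max_dist) {
  m <- as.matrix(manual); a <- as.matrix(auto)
  nm <- nrow(m); na <- nrow(a)
  d <- sqrt(outer(m[, 1], a[, 1], `-`)^2 + outer(m[, 2], a[, 2], `-`)^2)
  d[d > max_dist] <- NA
  best <- NULL; best_cost <- Inf; best_n <- -1L
  # enumerate which autos the manuals map to (including unmatched = 0)
  choices <- lapply(seq_len(nm), function(i) c(0L, which(!is.na(d[i, ]))))
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    sel <- as.integer(grid[r, ])
    nz <- sel[sel > 0]
    if (anyDuplicated(nz)) next
    cost <- sum(d[cbind(which(sel > 0), nz)])
    nmatch <- length(nz)
    if (nmatch > best_n || (nmatch == best_n && cost < best_cost)) {
      best_n <- nmatch; best_cost <- cost
      best <- cbind(manual = which(sel > 0), auto = nz)
    }
  }
  best
}

# --- direct per-pixel Phansalkar threshold with symmetric mirror
# padding, written as explicit loops over disk offsets
oracle_phansalkar <- function(m, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  nx <- nrow(m); ny <- ncol(m)
  reflect <- function(i, n) {
    i <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n) + 1
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  s1 <- matrix(0, nx, ny); s2 <- matrix(0, nx, ny)
  for (o in seq_len(nrow(off))) {
    ix <- reflect(seq_len(nx) + off$dx[o], nx)
    iy <- reflect(seq_len(ny) + off$dy[o], ny)
    v <- m[ix, iy, drop = FALSE]
    s1 <- s1 + v
    s2 <- s2 + v * v
  }
  mu <- s1 / nrow(off)
  sdv <- sqrt(pmax(s2 / nrow(off) - mu^2, 0))
  m > mu * (1 + p * exp(-q * mu) + k * (sdv / r - 1))
}

# --- brute-force Delaunay adjacency by the empty-circumcircle test
oracle_delaunay_pairs <- function(pts) {
  n <- nrow(pts)
  adj <- matrix(FALSE, n, n)
  circum <- function(a, b, c) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy)
  }
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ctr <- circum(pts[i, ], pts[j, ], pts[k, ])
    if (is.null(ctr)) next
    rad <- sqrt(sum((pts[i, ] - ctr)^2))
    others <- setdiff(seq_len(n), c(i, j, k))
    dd <- sqrt((pts[others, 1] - ctr[1])^2 + (pts[others, 2] - ctr[2])^2)
    if (all(dd > rad + 1e-9)) {
      adj[i, j] <- adj[j, i] <- TRUE
      adj[i, k] <- adj[k, i] <- TRUE
      adj[j, k] <- adj[k, j] <- TRUE
    }
  }
  which(adj & upper.tri(adj), arr.ind = TRUE)
}

# --- fixture builders ------------------------------------------------

# hard-edged grid mosaic: cells of `cell` px separated by `sep`-px
# bright stripes; returns list(pixels, stripe_mask)
grid_mosaic <- function(nx = 128, ny = 128, cell = 24, sep = 4,
                        lo = 0.1, hi = 0.9) {
  xi <- (seq_len(nx) - 1) %% (cell + sep) >= cell
  yi <- (seq_len(ny) - 1) %% (cell + sep) >= cell
  stripe <- outer(xi, yi, `|`)
  px <- matrix(lo, nx, ny)
  px[stripe] <- hi
  list(pixels = px, stripe_mask = stripe)
}

# Voronoi scene with constant-width septa around given seeds (direct
# geometric construction, independent of the package generator)
voronoi_scene <- function(seeds, nx, ny, width_px = 4, lo = 0.1, hi = 0.9) {
  px <- as.vector(row(matrix(0, nx, ny))) - 1
  py <- as.vector(col(matrix(0, nx, ny))) - 1
  n <- nrow(seeds)
  d <- sapply(seq_len(n), function(i) sqrt((px - seeds[i, 1])^2 + (py - seeds[i, 2])^2))
  ord1 <- max.col(-d)
  d1 <- d[cbind(seq_along(ord1), ord1)]
  d[cbind(seq_along(ord1), ord1)] <- Inf
  ord2 <- max.col(-d)
  d2 <- d[cbind(seq_along(ord2), ord2)]
  L <- sqrt((seeds[ord1, 1] - seeds[ord2, 1])^2 + (seeds[ord1, 2] - seeds[ord2, 2])^2)
  sdist <- (d1 + d2) * (d2 - d1) / (2 * L)
  scene <- matrix(ifelse(sdist < width_px / 2, hi, lo), nx, ny)
  list(pixels = scene, labels = matrix(ord1, nx, ny), mask = scene >= 0.5)
}

# myocyte_seg-shaped object from a plain label grid (for graph tests)
seg_from_labels <- function(labels, seeds) {
  records <- tibble::tibble(
    myocyte_id = seq_len(nrow(seeds)),
    seed_x_px = seeds[, 1], seed_y_px = seeds[, 2],
    centroid_x_px = seeds[, 1], centroid_y_px = seeds[, 2],
    area_um2 = 100, min_feret_um = 10,
    border_flag = FALSE, size_ok = TRUE
  )
  structure(list(records = records, labels = labels, prominence = 1,
                 image = NULL, mask = labels * 0 > 0),
            class = "myocyte_seg")
}

# bare measured graph (for CDI / clustering tests)
make_graph <- function(n, edges, widths = NULL) {
  e <- tibble::tibble(id_a = pmin(edges[, 1], edges[, 2]),
                      id_b = pmax(edges[, 1], edges[, 2]))
  if (!is.null(widths)) e$septum_width_um <- widths
  structure(list(nodes = tibble::tibble(myocyte_id = seq_len(n)), edges = e),
            class = "myocyte_graph")
}

# random simple graph as an edge matrix
random_graph <- function(n, p = 0.35) {
  all_e <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(all_e)) < p
  all_e[keep, , drop = FALSE]
}

# write a minimal uncompressed 24-bit BMP (bottom-up row order)
write_bmp24 <- function(px, path) {
  nx <- nrow(px); ny <- ncol(px)   # px in [0,1], [x, y] layout
  row_bytes <- ((3 * nx + 3) %/% 4) * 4
  data_size <- row_bytes * ny
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(c(54 + data_size, 0, 54)), con, size = 4, endian = "little")
  writeBin(as.integer(c(40, nx, ny)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 24)), con, size = 2, endian = "little")
  writeBin(as.integer(c(0, data_size, 2835, 2835, 0, 0)), con, size = 4, endian = "little")
  v <- round(px * 255)
  for (j in ny:1) {
    row <- as.vector(rbind(v[, j], v[, j], v[, j]))  # B, G, R identical
    row <- c(row, rep(0, row_bytes - 3 * nx))
    writeBin(as.raw(row), con)
  }
  invisible(path)
}
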