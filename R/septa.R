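#' Build the myocyte neighbour graph
#'
#' Two myocytes are direct neighbours when their watershed regions share
#' a boundary on the label grid (which tiles the whole image, so regions
#' separated only by the endomysial septum touch). A minimal contact of
#' `min_contact_px` 4-connected pixel pairs is required: two regions
#' that merely meet at a corner of the mosaic do not share a septum and
#' are not neighbours. The graph is simple and undirected; edges are
#' stored once with `id_a < id_b`.
#'
#' @param seg A `myocyte_seg` from [detect_myocytes()].
#' @param min_contact_px Minimal number of 4-connected boundary contact
#'   pixel pairs (roughly the shared boundary length in pixels).
#' @return An object of class `myocyte_graph`: list with `nodes` (the
#'   myocyte records), `edges` (tibble `id_a`, `id_b`, `contact_px`
#'   and, once measured, `septum_width_um`, `enhanced`) and the label
#'   grid.
#' @export
build_neighbor_graph <- function(seg, min_contact_px = 5L) {
  stopifnot(inherits(seg, "myocyte_seg"))
  lab <- seg$labels
  if (max(lab) > 0 && !all(sort(unique(as.integer(lab[lab > 0]))) %in% seg$records$myocyte_id)) {
    stop("label grid inconsistent with myocyte records", call. = FALSE)
  }
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ])),
    cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  edges <- tibble::tibble(id_a = integer(), id_b = integer(), contact_px = integer())
  if (nrow(pairs) > 0) {
    k <- max(lab) + 1
    key <- pmin(pairs[, 1], pairs[, 2]) * k + pmax(pairs[, 1], pairs[, 2])
    cnt <- table(key)
    keys <- as.numeric(names(cnt))
    keep <- as.integer(cnt) >= min_contact_px
    edges <- tibble::tibble(
      id_a = as.integer(keys[keep] %/% k),
      id_b = as.integer(keys[keep] %% k),
      contact_px = as.integer(cnt[keep])
    )
    edges <- edges[order(edges$id_a, edges$id_b), ]
  }
  structure(list(nodes = seg$records, edges = edges, labels = seg$labels, seg = seg),
            class = "myocyte_graph")
}

#' @export
print.myocyte_graph <- function(x, ...) {
  cat(sprintf("<myocyte_graph> %d nodes, %d edges%s\n",
              nrow(x$nodes), nrow(x$edges),
              if ("septum_width_um" %in% names(x$edges)) " (widths measured)" else ""))
  invisible(x)
}

#' @export
tidy.myocyte_graph <- function(x, ...) x$edges

#' Endomysial septum width between two neighbouring myocytes
#'
#' The WGA mask is sampled at sub-pixel steps (bilinear interpolation)
#' along a profile line through the point where the seed-to-seed
#' segment crosses the shared watershed boundary. The width is the
#' length of the contiguous WGA-positive run containing that crossing —
#' the width of the profile plot between the two cells — clipped where
#' the run strays into a third cell's territory (corner merges of
#' neighbouring septa). With `obliquity_correction` on (default) the
#' profile is taken perpendicular to the local septum orientation
#' (principal axis of the shared boundary pixels), so the thickness is
#' measured across the septum even when the seed chord crosses it
#' obliquely; switched off, the profile runs along the raw chord.
#' `septum_profile = "fwhm"` measures the full width at half maximum of
#' the raw intensity profile instead of the thresholded run.
#'
#' @param image The WGA [calibrated_image()].
#' @param mask Its [phansalkar_threshold()] mask.
#' @param graph A [build_neighbor_graph()] result.
#' @param id_a,id_b Myocyte ids of an edge of `graph`.
#' @param config An [analysis_config()].
#' @return Width in micrometres (0 when no WGA-positive pixel lies on
#'   the segment).
#' @export
septum_width <- function(image, mask, graph, id_a, id_b, config = analysis_config()) {
  stopifnot(inherits(graph, "myocyte_graph"))
  a <- min(id_a, id_b); b <- max(id_a, id_b)
  if (!any(graph$edges$id_a == a & graph$edges$id_b == b)) {
    stop("edge (", a, ", ", b, ") is not in the neighbour graph", call. = FALSE)
  }
  plane <- intensity_plane(image)
  stopifnot(identical(dim(plane), dim(mask)))
  nodes <- graph$nodes
  sa <- unlist(nodes[nodes$myocyte_id == a, c("seed_x_px", "seed_y_px")])
  sb <- unlist(nodes[nodes$myocyte_id == b, c("seed_x_px", "seed_y_px")])
  septum_width_one(plane, mask, graph$labels, sa, sb, a, b,
                   pixel_size_um(image), config)
}

#' Measure every septum of a neighbour graph
#'
#' @inheritParams septum_width
#' @return `graph` with `septum_width_um` filled in on its edges.
#' @export
measure_septa <- function(graph, image, mask, config = analysis_config()) {
  stopifnot(inherits(graph, "myocyte_graph"))
  plane <- intensity_plane(image)
  nodes <- graph$nodes
  upx <- pixel_size_um(image)
  seed_x <- setNames(nodes$seed_x_px, nodes$myocyte_id)
  seed_y <- setNames(nodes$seed_y_px, nodes$myocyte_id)
  w <- purrr::map2_dbl(graph$edges$id_a, graph$edges$id_b, function(a, b) {
    septum_width_one(plane, mask, graph$labels,
                     c(seed_x[[as.character(a)]], seed_y[[as.character(a)]]),
                     c(seed_x[[as.character(b)]], seed_y[[as.character(b)]]),
                     a, b, upx, config)
  })
  graph$edges$septum_width_um <- w
  graph
}

septum_width_one <- function(plane, mask, labels, seed_a, seed_b, a, b, upx, config) {
  chord <- seed_b - seed_a
  len_px <- sqrt(sum(chord^2))
  if (len_px == 0) return(0)
  step_px <- config$septum_step_px
  dir_chord <- chord / len_px
  bp <- boundary_pixels(labels, a, b)

  cross <- NULL
  dir <- dir_chord
  if (isTRUE(config$obliquity_correction) && nrow(bp) >= 3) {
    # measure at the middle of the shared boundary, perpendicular to its
    # principal axis: away from the corners where neighbouring septa
    # merge, and across the septum rather than obliquely through it
    ctr <- colMeans(bp)
    cc <- sweep(bp, 2, ctr)
    eg <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    if (eg$values[1] > eg$values[2] * (1 + 1e-9)) {
      tangent <- eg$vectors[, 1]
      proj <- cc %*% tangent
      cross <- bp[which.min(abs(proj - median(proj))), ]
      dir <- c(-tangent[2], tangent[1])
      if (sum(dir * dir_chord) < 0) dir <- -dir
    }
  }
  if (is.null(cross)) {
    # paper-literal profile: along the seed-to-seed chord, at the point
    # where it crosses the shared region boundary
    n_steps <- max(2L, ceiling(len_px / step_px))
    t <- seq(0, 1, length.out = n_steps + 1L)
    xs <- seed_a[1] + t * chord[1]
    ys <- seed_a[2] + t * chord[2]
    lab_line <- nearest_sample(labels, xs, ys)
    first_b <- match(b, lab_line)
    if (!is.na(first_b)) {
      last_a <- suppressWarnings(max(which(lab_line[seq_len(first_b)] == a)))
      if (is.finite(last_a) && all(lab_line[last_a:first_b] %in% c(a, b))) {
        ci <- round((last_a + first_b) / 2)
        cross <- c(xs[ci], ys[ci])
      }
    }
    if (is.null(cross)) {
      # chord strays through a third region: fall back to the shared
      # boundary pixel closest to the chord line
      if (nrow(bp) == 0) return(0)
      proj <- (bp[, 1] - seed_a[1]) * dir_chord[1] + (bp[, 2] - seed_a[2]) * dir_chord[2]
      perp <- abs((bp[, 1] - seed_a[1]) * dir_chord[2] - (bp[, 2] - seed_a[2]) * dir_chord[1])
      perp[proj < 0 | proj > len_px] <- Inf
      if (all(!is.finite(perp))) return(0)
      cross <- bp[which.min(perp), ]
    }
    dir <- dir_chord
  }

  s <- seq(-len_px / 2, len_px / 2, by = step_px)
  vx <- cross[1] + s * dir[1]
  vy <- cross[2] + s * dir[2]
  prof <- bilinear_sample(plane, vx, vy)
  if (config$septum_profile == "fwhm") {
    baseline <- min(prof[1], prof[length(prof)])
    on <- prof >= (baseline + max(prof)) / 2
  } else {
    on <- bilinear_sample(matrix(as.numeric(mask), nrow(mask), ncol(mask)), vx, vy) >= 0.5
  }
  # the run may not extend into territory of third regions (corner
  # merges of neighbouring septa)
  ok <- nearest_sample(labels, vx, vy) %in% c(a, b)

  z <- which.min(abs(s))
  if (!on[z]) {
    near <- which(on & abs(s) <= 2)
    if (length(near) == 0) return(0)
    z <- near[which.min(abs(s[near]))]
  }
  i0 <- z
  while (i0 > 1 && on[i0 - 1] && ok[i0 - 1]) i0 <- i0 - 1
  i1 <- z
  while (i1 < length(s) && on[i1 + 1] && ok[i1 + 1]) i1 <- i1 + 1
  width_px <- (s[i1] - s[i0]) + step_px

  if (config$septum_profile == "mask") {
    # refine both run endpoints to the sub-pixel half-maximum crossing
    # of the intensity profile: the binary mask locates the septum but
    # its edge is only pixel-accurate (and depends on where the local
    # threshold falls within the stained-to-unstained transition)
    peak <- max(prof[i0:i1])
    lo <- refine_edge(prof, s, i0, -1L, peak)
    hi <- refine_edge(prof, s, i1, +1L, peak)
    if (is.finite(lo) && is.finite(hi) && hi > lo &&
        abs((hi - lo) - width_px) <= 2) {
      width_px <- hi - lo
    }
  }
  width_px * upx
}

# sub-pixel position where the intensity profile crosses half way
# between the septum peak and the adjacent interior level, searching
# outward from run endpoint `i` in direction `dr`; NA when no clean
# crossing is found within 2 px
refine_edge <- function(prof, s, i, dr, peak) {
  step_px <- s[2] - s[1]
  span <- max(1L, ceiling(2 / step_px))
  out <- seq(i, by = dr, length.out = span + 1L)
  out <- out[out >= 1 & out <= length(prof)]
  if (length(out) < 2) return(NA_real_)
  base <- min(prof[out])
  half <- (peak + base) / 2
  below <- which(prof[out] < half)
  if (length(below) == 0) return(NA_real_)
  k <- out[below[1]]
  k_in <- k - dr
  if (k_in < 1 || k_in > length(prof) || prof[k_in] < half) return(s[k])
  frac <- (prof[k_in] - half) / (prof[k_in] - prof[k])
  s[k_in] + dr * frac * step_px
}

boundary_pixels <- function(labels, a, b) {
  nx <- nrow(labels); ny <- ncol(labels)
  hits <- matrix(FALSE, nx, ny)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    sh <- shift_mat(labels, d[1], d[2])
    hits <- hits | (labels == a & sh == b) | (labels == b & sh == a)
    sh <- shift_mat(labels, -d[1], -d[2])
    hits <- hits | (labels == a & sh == b) | (labels == b & sh == a)
  }
  idx <- which(hits)
  cbind(x = (idx - 1) %% nx, y = (idx - 1) %/% nx)
}

#' Reference septum statistics
#'
#' Mean and standard deviation of endomysial septum widths in reference
#' (structurally healthy) tissue. An inter-myocyte distance is
#' "enhanced" when it exceeds `mu + 2 sd`.
#'
#' @param mu_um,sd_um Reference mean and standard deviation in
#'   micrometres.
#' @param source_note Free-text provenance of the reference.
#' @return An object of class `reference_stats`.
#' @export
reference_stats <- function(mu_um, sd_um, source_note = "user-supplied") {
  stopifnot(is.numeric(mu_um), is.numeric(sd_um), mu_um > 0, sd_um >= 0)
  structure(list(mu_um = mu_um, sd_um = sd_um, source_note = source_note),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> mu %.3g um, sd %.3g um (enhanced > %.3g um) [%s]\n",
              x$mu_um, x$sd_um, enhancement_threshold(x), x$source_note))
  invisible(x)
}

#' Enhancement threshold of a reference
#' @param ref A [reference_stats()].
#' @return `mu + 2 sd` in micrometres.
#' @export
enhancement_threshold <- function(ref) ref$mu_um + 2 * ref$sd_um

#' Estimate reference septum statistics from measured graphs
#'
#' Pools every measured edge width over the supplied reference images
#' and returns their mean and sample standard deviation (n - 1).
#'
#' @param graphs A list of measured [myocyte_graph]s (or numeric width
#'   vectors).
#' @param source_note Provenance note stored with the result.
#' @return A [reference_stats()].
#' @export
estimate_reference <- function(graphs, source_note = "estimated from reference images") {
  if (inherits(graphs, "myocyte_graph") || is.numeric(graphs)) graphs <- list(graphs)
  widths <- unlist(lapply(graphs, function(g) {
    if (inherits(g, "myocyte_graph")) {
      if (!"septum_width_um" %in% names(g$edges)) {
        stop("graph has unmeasured edges; run measure_septa() first", call. = FALSE)
      }
      g$edges$septum_width_um
    } else {
      as.numeric(g)
    }
  }))
  widths <- widths[is.finite(widths)]
  if (length(widths) < 10) {
    stop("need at least 10 pooled edge widths for a stable reference", call. = FALSE)
  }
  reference_stats(mean(widths), stats::sd(widths), source_note)
}

#' Cardiomyocyte dissociation index (CDI)
#'
#' For each myocyte, the fraction of its inter-myocyte distances
#' (septum widths to direct neighbours) that exceed the reference mean
#' by more than two standard deviations. CDI is 0 for a cell closely
#' apposed to all neighbours and 1 for a cell isolated from all of them.
#' Cells without neighbours are flagged undefined (`cdi = NA`) and
#' excluded from the image mean.
#'
#' @param graph A measured [myocyte_graph] (see [measure_septa()]).
#' @param ref A [reference_stats()].
#' @return An object of class `cdi_result`: list with `records`
#'   (tibble `myocyte_id`, `n_neighbors`, `n_enhanced`, `cdi`),
#'   `mean_cdi`, `threshold_um`, and the input graph with `enhanced`
#'   set on its edges.
#' @export
compute_cdi <- function(graph, ref) {
  stopifnot(inherits(graph, "myocyte_graph"), inherits(ref, "reference_stats"))
  if (!"septum_width_um" %in% names(graph$edges)) {
    stop("graph has unmeasured edges; run measure_septa() first", call. = FALSE)
  }
  thr <- enhancement_threshold(ref)
  edges <- graph$edges
  edges$enhanced <- edges$septum_width_um > thr
  ids <- graph$nodes$myocyte_id
  deg <- setNames(integer(length(ids)), ids)
  enh <- setNames(integer(length(ids)), ids)
  for (col in c("id_a", "id_b")) {
    tb <- table(factor(edges[[col]], levels = ids))
    deg <- deg + as.integer(tb)
    tbe <- table(factor(edges[[col]][edges$enhanced], levels = ids))
    enh <- enh + as.integer(tbe)
  }
  records <- tibble::tibble(
    myocyte_id = ids,
    n_neighbors = as.integer(deg),
    n_enhanced = as.integer(enh),
    cdi = unname(ifelse(deg > 0, enh / deg, NA_real_))
  )
  graph$edges <- edges
  structure(list(records = records,
                 mean_cdi = mean(records$cdi, na.rm = TRUE),
                 threshold_um = thr,
                 graph = graph),
            class = "cdi_result")
}

#' @export
print.cdi_result <- function(x, ...) {
  cat(sprintf("<cdi_result> %d cells, mean CDI %.3f (enhanced > %.3g um)\n",
              nrow(x$records), x$mean_cdi, x$threshold_um))
  invisible(x)
}

#' @export
tidy.cdi_result <- function(x, ...) x$records

#' @export
glance.cdi_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$records),
    mean_cdi = x$mean_cdi,
    frac_cdi_ge_50 = mean(x$records$cdi >= 0.5, na.rm = TRUE),
    threshold_um = x$threshold_um
  )
}
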