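#' Write structure records to CSV
#'
#' One row per recognised structure, positions in pixels (0-based,
#' origin top-left, x = column) and sizes in micrometres, as the column
#' names state. Values survive a read-back round trip to at least six
#' significant digits.
#'
#' @param records A data frame (possibly empty) of structure records.
#' @param out_path Output CSV path.
#' @return Invisibly, `out_path`.
#' @export
write_records_csv <- function(records, out_path) {
  tryCatch(
    utils::write.csv(as.data.frame(records), out_path, row.names = FALSE),
    error = function(e) stop("cannot write CSV: ", out_path, " (", conditionMessage(e), ")",
                             call. = FALSE)
  )
  invisible(out_path)
}

#' Read back a structure CSV
#' @param path CSV path written by [write_records_csv()].
#' @return A tibble.
#' @export
read_records_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Control overlay and CDI heat map images
#'
#' Writes two PNG renderings for visual inspection of segmentation
#' accuracy: `<prefix>_overlay.png` shows the thresholded membranes
#' (red) over the original intensity, the minimal-Feret segment of each
#' myocyte (green) and the neighbour line selections between seed
#' minima (yellow); `<prefix>_cdi.png` fills each myocyte with a colour
#' mapping CDI 0 (white, closely apposed) to 1 (dark red, isolated).
#'
#' @param image The WGA [calibrated_image()].
#' @param graph A measured [myocyte_graph] derived from `image`.
#' @param cdi A [compute_cdi()] result (may be `NULL` to skip the heat
#'   map).
#' @param out_prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_overlay <- function(image, graph, cdi, out_prefix) {
  stopifnot(inherits(image, "calibrated_image"), inherits(graph, "myocyte_graph"))
  plane <- intensity_plane(image)
  if (!identical(dim(plane), dim(graph$labels))) {
    stop("image and graph dimensions do not match", call. = FALSE)
  }
  mask <- graph$seg$mask
  nx <- nrow(plane); ny <- ncol(plane)
  r <- g <- b <- plane * 0.6
  r[mask] <- pmin(1, plane[mask] * 0.4 + 0.6)
  g[mask] <- plane[mask] * 0.25
  b[mask] <- plane[mask] * 0.25

  nodes <- graph$nodes
  sets <- label_pixel_sets(graph$labels * !mask)
  for (i in seq_len(nrow(nodes))) {
    if (!nodes$size_ok[i]) next
    s <- sets[[as.character(nodes$myocyte_id[i])]]
    if (is.null(s) || nrow(s) < 3) next
    info <- min_feret_info(cbind(s$x, s$y))
    if (is.null(info)) next
    half <- info$width_px / 2
    cx <- nodes$centroid_x_px[i]; cy <- nodes$centroid_y_px[i]
    g <- draw_segment(g, cx - info$normal[1] * half, cy - info$normal[2] * half,
                      cx + info$normal[1] * half, cy + info$normal[2] * half, 1)
    r <- draw_segment(r, cx - info$normal[1] * half, cy - info$normal[2] * half,
                      cx + info$normal[1] * half, cy + info$normal[2] * half, 0.1)
  }
  if (nrow(graph$edges) > 0) {
    sx <- setNames(nodes$seed_x_px, nodes$myocyte_id)
    sy <- setNames(nodes$seed_y_px, nodes$myocyte_id)
    for (e in seq_len(nrow(graph$edges))) {
      a <- as.character(graph$edges$id_a[e]); bb <- as.character(graph$edges$id_b[e])
      r <- draw_segment(r, sx[[a]], sy[[a]], sx[[bb]], sy[[bb]], 1)
      g <- draw_segment(g, sx[[a]], sy[[a]], sx[[bb]], sy[[bb]], 0.9)
      b <- draw_segment(b, sx[[a]], sy[[a]], sx[[bb]], sy[[bb]], 0.1)
    }
  }
  arr <- array(0, c(nx, ny, 3)); arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  overlay_path <- paste0(out_prefix, "_overlay.png")
  write_image(arr, overlay_path)
  paths <- overlay_path

  if (!is.null(cdi)) {
    stopifnot(inherits(cdi, "cdi_result"))
    ramp <- grDevices::colorRamp(c("white", "darkred"))
    r2 <- g2 <- b2 <- matrix(0.15, nx, ny)
    r2[mask] <- 0.45; g2[mask] <- 0.45; b2[mask] <- 0.45
    for (i in seq_len(nrow(cdi$records))) {
      s <- sets[[as.character(cdi$records$myocyte_id[i])]]
      if (is.null(s)) next
      v <- cdi$records$cdi[i]
      col <- if (is.na(v)) c(120, 120, 120) else ramp(v)
      idx <- cbind(s$x + 1, s$y + 1)
      r2[idx] <- col[1] / 255; g2[idx] <- col[2] / 255; b2[idx] <- col[3] / 255
    }
    arr2 <- array(0, c(nx, ny, 3)); arr2[, , 1] <- r2; arr2[, , 2] <- g2; arr2[, , 3] <- b2
    cdi_path <- paste0(out_prefix, "_cdi.png")
    write_image(arr2, cdi_path)
    paths <- c(paths, cdi_path)
  }
  invisible(paths)
}

#' Analyse one (multi-channel) micrograph
#'
#' Runs the full per-image pipeline on whichever channels are supplied:
#' WGA thresholding, fibrosis fraction, myocyte segmentation, neighbour
#' graph and septum widths, CDI, clustering permutation test; capillary
#' detection on the endothelial channel; fibroblast counting on the
#' vimentin channel (after endothelial subtraction when available).
#'
#' @param wga,endothelial,fibroblast [calibrated_image()]s (any may be
#'   `NULL`).
#' @param config An [analysis_config()].
#' @param reference Optional [reference_stats()]; when `NULL`, taken
#'   from the config, or estimated from this image's own pooled edges
#'   as a last resort.
#' @param image_id Identifier used in the output tables.
#' @return A list of class `image_analysis`: tibbles `summary` (one
#'   row), `myocytes`, `septa`, `cdi`, `capillaries`, `fibroblasts`,
#'   `clustering`, plus the underlying `seg`, `graph`, `cdi_result`,
#'   `clustering_result` objects.
#' @export
analyze_image <- function(wga = NULL, endothelial = NULL, fibroblast = NULL,
                          config = analysis_config(), reference = NULL,
                          image_id = NULL) {
  if (is.null(wga) && is.null(endothelial) && is.null(fibroblast)) {
    stop("supply at least one channel image", call. = FALSE)
  }
  image_id <- image_id %||% (wga %||% endothelial %||% fibroblast)$source_id

  seg <- graph <- cdi_res <- clust <- NULL
  fibrosis <- NA_real_
  myocytes <- septa <- cdi_tab <- NULL
  if (!is.null(wga)) {
    mask <- phansalkar_threshold(wga, config = config)
    fibrosis <- fibrosis_fraction(mask)
    seg <- detect_myocytes(wga, mask, config)
    graph <- build_neighbor_graph(seg, config$neighbor_min_contact_px)
    graph <- measure_septa(graph, wga, mask, config)
    if (is.null(reference)) {
      reference <- if (is.finite(config$reference_mu_um) && is.finite(config$reference_sd_um)) {
        reference_stats(config$reference_mu_um, config$reference_sd_um, "config")
      } else if (nrow(graph$edges) >= 10) {
        estimate_reference(graph, "estimated from this image")
      } else NULL
    }
    myocytes <- dplyr::mutate(seg$records, image_id = image_id, .before = 1)
    septa <- dplyr::mutate(graph$edges, image_id = image_id, .before = 1)
    if (!is.null(reference) && nrow(graph$edges) > 0) {
      cdi_res <- compute_cdi(graph, reference)
      graph <- cdi_res$graph
      septa <- dplyr::mutate(graph$edges, image_id = image_id, .before = 1)
      cdi_tab <- dplyr::mutate(cdi_res$records, image_id = image_id, .before = 1)
      if (cdi_res$mean_cdi > 0 && sum(graph$edges$enhanced) > 0) {
        clust <- permutation_test(graph, reference,
                                  n_permutations = config$n_permutations,
                                  seed = config$seed)
      }
    }
  }

  capillaries <- fibroblasts <- NULL
  endo_mask <- NULL
  res <- (wga %||% endothelial %||% fibroblast)$resolution_px_per_mm
  if (!is.null(endothelial)) {
    endo_mask <- hsb_threshold(endothelial, config$hsb_hue_range_deg,
                               config$hsb_sat_min, config$hsb_bright_min,
                               config$blur_sigma_px)
    capillaries <- detect_capillaries(endo_mask, endothelial$resolution_px_per_mm,
                                      config$capillary_min_area_um2,
                                      config$capillary_circularity)
    capillaries <- dplyr::mutate(capillaries, image_id = image_id, .before = 1)
  }
  if (!is.null(fibroblast)) {
    vim_mask <- hsb_threshold(fibroblast, config$hsb_hue_range_fibro_deg,
                              config$hsb_sat_min, config$hsb_bright_min,
                              config$blur_sigma_px)
    if (is.null(endo_mask)) {
      warning("no endothelial channel: fibroblast count not corrected for ",
              "endothelial vimentin cross-reactivity")
      endo_mask_use <- vim_mask & FALSE
    } else {
      endo_mask_use <- endo_mask
    }
    fibroblasts <- fibroblast_count(vim_mask, endo_mask_use,
                                    fibroblast$resolution_px_per_mm,
                                    config$fibroblast_min_area_um2)
    fibroblasts <- dplyr::mutate(fibroblasts, image_id = image_id, .before = 1)
  }

  n_myo <- if (is.null(seg)) NA_integer_ else nrow(seg$records)
  ratio <- function(nn) {
    if (is.na(n_myo) || is.null(nn)) NA_real_ else if (n_myo > 0) nn / n_myo else NA_real_
  }
  sized <- if (is.null(seg)) NULL else seg$records[seg$records$size_ok, ]
  summary <- tibble::tibble(
    image_id = image_id,
    fibrosis_fraction = fibrosis,
    myocyte_count = n_myo,
    median_min_feret_um = if (!is.null(sized) && nrow(sized) > 0)
      median(sized$min_feret_um) else NA_real_,
    median_septum_width_um = if (!is.null(graph) && nrow(graph$edges) > 0)
      median(graph$edges$septum_width_um) else NA_real_,
    mean_cdi = if (!is.null(cdi_res)) cdi_res$mean_cdi else NA_real_,
    observed_cc = if (!is.null(clust)) clust$observed_cc else NA_real_,
    expected_cc = if (!is.null(clust)) clust$expected_cc else NA_real_,
    cc_p_score = if (!is.null(clust)) clust$p_score else NA_real_,
    capillary_count = if (is.null(capillaries)) NA_integer_ else nrow(capillaries),
    capillaries_per_myocyte = ratio(if (is.null(capillaries)) NULL else nrow(capillaries)),
    median_capillary_feret_um = if (!is.null(capillaries) && any(capillaries$transverse))
      median(capillaries$min_feret_um[capillaries$transverse]) else NA_real_,
    fibroblast_count = if (is.null(fibroblasts)) NA_integer_ else nrow(fibroblasts),
    fibroblasts_per_myocyte = ratio(if (is.null(fibroblasts)) NULL else nrow(fibroblasts))
  )

  structure(list(
    summary = summary, myocytes = myocytes, septa = septa, cdi = cdi_tab,
    capillaries = capillaries, fibroblasts = fibroblasts,
    clustering = if (!is.null(clust)) {
      dplyr::mutate(glance(clust), image_id = image_id, .before = 1)
    } else NULL,
    seg = seg, graph = graph, cdi_result = cdi_res, clustering_result = clust,
    reference = reference
  ), class = "image_analysis")
}

#' @export
print.image_analysis <- function(x, ...) {
  cat("<image_analysis>", x$summary$image_id, "\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Batch analysis of channel folders
#'
#' Analyses every image of one to three channel folders (WGA,
#' endothelial, fibroblast), matching channels of one micrograph across
#' folders by base filename (case-insensitive, extension stripped).
#' When no reference septum statistics are configured, they are
#' estimated once from all measured edges pooled over the batch, then
#' CDI and clustering are computed per image. Per-structure CSVs,
#' control overlays and a one-row-per-image summary table are written
#' to `out_dir`; the run is deterministic given the config seed and
#' needs no interactive input.
#'
#' @param wga_dir,endothelial_dir,fibroblast_dir Channel folders (any
#'   may be `NULL`, at least one must be supplied).
#' @param out_dir Output folder (created if missing).
#' @param resolution_px_per_mm Spatial calibration of all images.
#' @param config An [analysis_config()].
#' @param reference Optional [reference_stats()] overriding config /
#'   batch estimation.
#' @param overlays Write control overlay images.
#' @param progress Print percentage progress messages.
#' @return A tibble with one summary row per analysed image.
#' @export
run_batch <- function(wga_dir = NULL, endothelial_dir = NULL, fibroblast_dir = NULL,
                      out_dir, resolution_px_per_mm,
                      config = analysis_config(), reference = NULL,
                      overlays = TRUE, progress = TRUE) {
  dirs <- list(wga = wga_dir, endothelial = endothelial_dir, fibroblast = fibroblast_dir)
  dirs <- dirs[!vapply(dirs, is.null, logical(1))]
  if (length(dirs) == 0) stop("supply at least one channel folder", call. = FALSE)
  exts <- "\\.(tif|tiff|png|jpg|jpeg|bmp)$"
  listings <- lapply(dirs, function(d) {
    f <- list.files(d, pattern = exts, ignore.case = TRUE, full.names = TRUE)
    setNames(f, tolower(tools::file_path_sans_ext(basename(f))))
  })
  if (all(vapply(listings, length, integer(1)) == 0)) {
    stop("no images found in the supplied folders", call. = FALSE)
  }
  all_bases <- sort(unique(unlist(lapply(listings, names))))
  common <- Reduce(intersect, lapply(listings, names))
  skipped <- setdiff(all_bases, common)
  for (s in skipped) {
    warning("image '", s, "' not present in every supplied channel folder; skipped")
  }
  if (length(common) == 0) stop("no base filenames match across the supplied folders",
                                call. = FALSE)
  common <- sort(common)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  load_one <- function(role, base) {
    if (is.null(listings[[role]])) return(NULL)
    load_channel(listings[[role]][[base]], resolution_px_per_mm, role)
  }

  # pass 1: segment + measure so the reference can pool the whole batch
  if (is.null(reference) &&
      is.finite(config$reference_mu_um) && is.finite(config$reference_sd_um)) {
    reference <- reference_stats(config$reference_mu_um, config$reference_sd_um, "config")
  }
  analyses <- vector("list", length(common))
  need_pooled_ref <- is.null(reference) && "wga" %in% names(dirs)
  if (need_pooled_ref) {
    graphs <- list()
    for (i in seq_along(common)) {
      wga <- load_one("wga", common[i])
      mask <- phansalkar_threshold(wga, config = config)
      seg <- detect_myocytes(wga, mask, config)
      g <- measure_septa(build_neighbor_graph(seg, config$neighbor_min_contact_px),
                         wga, mask, config)
      graphs[[i]] <- g
      if (progress) message(sprintf("reference pass: %d%% of images measured",
                                    round(100 * i / length(common))))
    }
    reference <- estimate_reference(graphs, "pooled over batch")
  }

  for (i in seq_along(common)) {
    base <- common[i]
    analyses[[i]] <- analyze_image(
      wga = load_one("wga", base),
      endothelial = load_one("endothelial", base),
      fibroblast = load_one("fibroblast", base),
      config = config, reference = reference, image_id = base
    )
    if (overlays && !is.null(analyses[[i]]$graph)) {
      write_overlay(analyses[[i]]$seg$image, analyses[[i]]$graph,
                    analyses[[i]]$cdi_result,
                    file.path(out_dir, base))
    }
    if (progress) message(sprintf("analysis: %d%% of images analyzed",
                                  round(100 * i / length(common))))
  }

  gather <- function(field) {
    tabs <- purrr::compact(lapply(analyses, `[[`, field))
    if (length(tabs)) dplyr::bind_rows(tabs) else tibble::tibble()
  }
  write_records_csv(gather("myocytes"), file.path(out_dir, "myocytes.csv"))
  write_records_csv(gather("septa"), file.path(out_dir, "septa.csv"))
  write_records_csv(gather("cdi"), file.path(out_dir, "cdi.csv"))
  write_records_csv(gather("capillaries"), file.path(out_dir, "capillaries.csv"))
  write_records_csv(gather("fibroblasts"), file.path(out_dir, "fibroblasts.csv"))
  write_records_csv(gather("clustering"), file.path(out_dir, "clustering.csv"))
  summary <- gather("summary")
  write_records_csv(summary, file.path(out_dir, "summary.csv"))
  summary
}
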