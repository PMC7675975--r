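#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one flat list. The defaults
#' reproduce the published constants where the method states them (1000
#' permutations; 1.5 um^2 minimal capillary area; 0.35 circularity gate)
#' and otherwise use the values documented in the methods vignette.
#'
#' @param phansalkar_radius_px Window radius of the Phansalkar local
#'   threshold, in pixels. Should scale with magnification.
#' @param phansalkar_k,phansalkar_r,phansalkar_p,phansalkar_q Phansalkar
#'   constants of `t = m (1 + p e^(-q m) + k (s/r - 1))`.
#' @param blur_sigma_px Gaussian blur sigma applied before myocyte seed
#'   detection and before the HSB colour threshold.
#' @param contrast_scale Multiplier mapping the mean WGA-positive /
#'   -negative contrast to the seed-detection prominence (the minimum
#'   dynamic an intensity minimum must have to seed a cell).
#' @param surround_r_inner_px,surround_r_outer_px,surround_max_fraction
#'   Annulus and WGA-positive fraction above which a candidate minimum is
#'   rejected as lying inside fibrosis (the red-surround rule).
#' @param min_cell_area_um2 Regions smaller than this are excluded from
#'   size statistics (they remain graph nodes).
#' @param neighbor_min_contact_px Minimal shared-boundary contact (in
#'   4-connected pixel pairs) for two regions to count as direct
#'   neighbours; corner touches are not neighbour relations.
#' @param septum_step_px Sub-pixel sampling step of the inter-myocyte
#'   line profile.
#' @param septum_profile One of `"mask"` (width of the contiguous
#'   thresholded run crossing the boundary; default) or `"fwhm"`
#'   (full width at half maximum on the raw intensity profile).
#' @param obliquity_correction Take the profile perpendicular to the
#'   local septum orientation through the middle of the shared
#'   boundary, measuring the septum thickness proper; switched off, the
#'   profile runs along the raw seed-to-seed chord and overestimates
#'   obliquely crossed septa.
#' @param reference_mu_um,reference_sd_um Reference mean and standard
#'   deviation of septum widths; an edge is "enhanced" when wider than
#'   `mu + 2 sd`. `NA` means: estimate from the batch (pooled edges).
#' @param n_permutations Permutations for the clustering null.
#' @param seed Random seed for every stochastic step.
#' @param hsb_hue_range_deg Hue interval (degrees, circular) of the
#'   endothelial colour threshold.
#' @param hsb_hue_range_fibro_deg Hue interval for the vimentin channel.
#' @param hsb_sat_min,hsb_bright_min Saturation / brightness floors.
#' @param capillary_min_area_um2 Minimal capillary area.
#' @param capillary_circularity Circularity gate selecting transversely
#'   cut capillaries for Feret sizing.
#' @param fibroblast_min_area_um2 Minimal fibroblast component area after
#'   endothelial subtraction.
#' @param match_max_dist_px Centroid-matching distance cap for
#'   validation; `NA` means: half the median myocyte minimal Feret.
#'
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(phansalkar_radius_px = 15L,
                            phansalkar_k = 0.25,
                            phansalkar_r = 0.5,
                            phansalkar_p = 2.0,
                            phansalkar_q = 10.0,
                            blur_sigma_px = 2,
                            contrast_scale = 0.5,
                            surround_r_inner_px = 2,
                            surround_r_outer_px = 6,
                            surround_max_fraction = 0.6,
                            min_cell_area_um2 = 20,
                            neighbor_min_contact_px = 5L,
                            septum_step_px = 0.25,
                            septum_profile = c("mask", "fwhm"),
                            obliquity_correction = TRUE,
                            reference_mu_um = NA_real_,
                            reference_sd_um = NA_real_,
                            n_permutations = 1000L,
                            seed = 1L,
                            hsb_hue_range_deg = c(80, 160),
                            hsb_hue_range_fibro_deg = c(200, 280),
                            hsb_sat_min = 0.15,
                            hsb_bright_min = 0.15,
                            capillary_min_area_um2 = 1.5,
                            capillary_circularity = 0.35,
                            fibroblast_min_area_um2 = 1.5,
                            match_max_dist_px = NA_real_) {
  septum_profile <- match.arg(septum_profile)
  cfg <- as.list(environment())
  stopifnot(cfg$phansalkar_radius_px >= 1, cfg$phansalkar_r > 0,
            cfg$n_permutations >= 1, cfg$septum_step_px > 0)
  structure(cfg, class = c("analysis_config", "list"))
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns an [analysis_config()];
#'   `write_config()` invisibly returns `path`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param config An [analysis_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
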