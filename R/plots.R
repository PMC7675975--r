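# ggplot2 views of the main result types; file-based control images are
# produced by write_overlay().

#' @export
autoplot.myocyte_seg <- function(object, ...) {
  df <- object$records
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centroid_x_px, y = .data$centroid_y_px)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$min_feret_um,
                                     colour = .data$size_ok), alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey60")) +
    ggplot2::labs(x = "x (px)", y = "y (px)", size = "min Feret (um)",
                  colour = "in size stats",
                  title = sprintf("%d myocytes", nrow(df))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cdi_result <- function(object, ...) {
  lab <- object$graph$labels
  mask <- object$graph$seg$mask
  cell_lab <- lab * !mask
  idx <- which(cell_lab > 0)
  cdi_of <- setNames(object$records$cdi, object$records$myocyte_id)
  df <- tibble::tibble(
    x = (idx - 1) %% nrow(lab),
    y = (idx - 1) %/% nrow(lab),
    cdi = unname(cdi_of[as.character(cell_lab[idx])])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$cdi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1), na.value = "grey70") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "CDI",
                  title = sprintf("mean CDI %.3f", object$mean_cdi)) +
    ggplot2::theme_minimal()
}
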