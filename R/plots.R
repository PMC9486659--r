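#' Plot an axial slice of every parameter map
#'
#' @param object a `dmi_maps`.
#' @param z slice index (default: middle slice).
#' @param ... unused.
#' @return a faceted ggplot of the parameter fields.
#' @export
autoplot.dmi_maps <- function(object, z = NULL, ...) {
  dims <- dim(object$mask)
  if (is.null(z)) z <- ceiling(dims[3] / 2)
  zslice <- z
  df <- tidy(object) |>
    dplyr::filter(.data$z == zslice) |>
    tidyr::pivot_longer(-c("x", "y", "z"), names_to = "parameter",
                        values_to = "value") |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = c(DMI_PARAMS, "adc")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("axial slice z = %d", z),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot lesion vs contralateral descriptive statistics
#'
#' Point-and-errorbar summary (mean with 5th/95th percentile bars) of each
#' model parameter inside the lesion and its mirrored contralateral region.
#'
#' @param stats tibble from [lesion_statistics()].
#' @return a ggplot.
#' @export
plot_lesion_statistics <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$region, y = .data$mean,
                                      colour = .data$region)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                           width = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(y = "value (fractions unitless, diffusivities µm²/ms)",
                  x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
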