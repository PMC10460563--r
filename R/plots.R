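#' Plot an outline trace
#'
#' Shows the traced (or smoothed) boundary in image coordinates, with the
#' vertical axis flipped so the plot matches the image orientation.
#'
#' @param object An `mb_outline`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_outline <- function(object, ...) {
  ggplot(object, aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (px)", y = "v (px)",
                  title = paste0(attr(object, "view_tag") %||% "outline",
                                 " trace")) +
    ggplot2::theme_minimal()
}

#' Plot an axial profile
#'
#' Dorsoventral and transverse diameters against the body-axis station;
#' the two curves are the per-station section semi-axis diameters that the
#' body mesher turns into superellipses.
#'
#' @param object An `mb_axial_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_axial_profile <- function(object, ...) {
  long <- tibble::tibble(
    z_px = rep(object$z_px, 2),
    diameter_px = c(object$dv_diameter_px, object$tv_diameter_px),
    axis = rep(c("dorsoventral", "transverse"), each = nrow(object)))
  ggplot(long, aes(x = .data$z_px, y = .data$diameter_px,
                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "body axis station (px)", y = "diameter (px)") +
    ggplot2::theme_minimal()
}

#' Plot the bracketed totals of a model report
#'
#' Volume per component for the low- and high-exponent models; the gap
#' between the two body bars is the bracketing interval.
#'
#' @param object An `mb_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_report <- function(object, ...) {
  ggplot(object$sections,
         aes(x = .data$component, y = .data$volume_m3, fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = expression(volume ~ (m^3)),
                  fill = "exponent model") +
    ggplot2::theme_minimal()
}
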