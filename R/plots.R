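#' Arrow plot of a binned flow field
#'
#' In-plane (x--y) arrow field of the binned mean velocities, the standard
#' view of the near-field flow between the two brushes.
#'
#' @param object a `flow_grid` from [bin_velocities()].
#' @param arrow_scale arrow length per unit velocity (r_c per r_c/tau).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.flow_grid <- function(object, arrow_scale = NULL, ...) {
  g <- object[object$occupied, ]
  if (is.null(arrow_scale)) {
    sp <- max(g$speed, na.rm = TRUE)
    h <- attr(object, "box") / attr(object, "grid")
    arrow_scale <- if (sp > 0) 0.8 * min(h[1:2]) / sp else 1
  }
  ggplot2::ggplot(g, ggplot2::aes(x = .data$x_mid, y = .data$y_mid)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x_mid + arrow_scale * .data$vx,
                   yend = .data$y_mid + arrow_scale * .data$vy,
                   colour = .data$speed),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (r_c)", y = "y (r_c)", colour = "|v|") +
    ggplot2::theme_minimal()
}

#' Deflection time series of the brush chains
#'
#' @param object a `dpd_run`.
#' @param relative plot the contour-normalised deflection.
#' @param ... passed to [tip_deflection()] / [relative_deflection()].
#' @return A ggplot.
#' @export
autoplot.dpd_run <- function(object, relative = FALSE, ...) {
  if (relative) {
    d <- relative_deflection(object, each = TRUE, ...)
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$rel_deflection,
                                         colour = factor(.data$chain))) +
      ggplot2::labs(y = expression(Delta * x / l[0]))
  } else {
    d <- tip_deflection(object, ...)
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$dx,
                                         colour = factor(.data$chain))) +
      ggplot2::labs(y = expression(Delta * x ~ "(r_c)"))
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (tau)", colour = "chain") +
    ggplot2::theme_minimal()
}

#' Shear profile plot
#'
#' @param profile a tibble from [shear_profile()].
#' @return A ggplot with the streamwise velocity and shear rate by height.
#' @export
plot_shear_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile[, c("y_mid", "vx", "shear_rate")],
                              c("vx", "shear_rate"),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$y_mid)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "y (r_c)") +
    ggplot2::theme_minimal()
}
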