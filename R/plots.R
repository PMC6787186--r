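# ggplot2 graphics for trajectories and fits

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chain trajectory
#'
#' Bead paths in the surface plane, coloured by time; for stripe or
#' boundary patterns the strongly binding material is shaded.
#'
#' @param object A `bd_trajectory`.
#' @param every Plot every this-many frames (thinning).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bd_trajectory <- function(object, every = 1, ...) {
  tr <- dplyr::filter(object, .data$frame %% every == 0 |
                        .data$frame == min(.data$frame))
  p <- ggplot2::ggplot(tr, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$frame,
                                    colour = .data$time),
                       linewidth = 0.3, alpha = 0.7) +
    ggplot2::scale_colour_viridis_c(name = "time (ns)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  prov <- trajectory_provenance(object)
  pat <- prov$pattern
  if (!is.null(pat) && pat$geometry == "stripe") {
    p <- p + ggplot2::annotate("rect",
      xmin = -Inf, xmax = Inf,
      ymin = -pat$stripe_width / 2, ymax = pat$stripe_width / 2,
      alpha = 0.12, fill = "steelblue")
  } else if (!is.null(pat) && pat$geometry == "single_boundary") {
    p <- p + ggplot2::geom_vline(xintercept = 0, linetype = 2,
                                 colour = "steelblue")
  }
  p
}

#' Plot a persistence-length fit
#'
#' Log tangent correlation against contour separation with the fitted
#' exponential-decay line; the slope gives -1/lp.
#'
#' @param object A `persistence_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.persistence_fit <- function(object, ...) {
  d <- dplyr::filter(object$correlations, .data$correlation > 0)
  d$na <- d$separation * object$spacing
  in_fit <- d$separation >= object$fit_range[1] &
    d$separation <= object$fit_range[2]
  ggplot2::ggplot(d, ggplot2::aes(.data$na, log(.data$correlation))) +
    ggplot2::geom_point(ggplot2::aes(shape = in_fit)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "in fit range") +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = stats::coef(object$fit)[1],
                         colour = "firebrick") +
    ggplot2::labs(
      x = "contour separation N a (nm)",
      y = expression(ln ~ group("<", cos ~ theta, ">")),
      subtitle = sprintf("lp = %.3f nm", object$lp)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a diffusion fit
#'
#' MSD curve with the fitted line over the fit window; the slope is 2D.
#'
#' @param object A `diffusion_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  d <- object$msd
  cf <- stats::coef(object$fit)
  ggplot2::ggplot(d, ggplot2::aes(.data$lag, .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = object$fit_window[1],
                      xmax = object$fit_window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "steelblue") +
    ggplot2::geom_abline(intercept = cf[1], slope = cf[2],
                         colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = expression(Delta * t ~ "(ns)"),
                  y = expression(group("<", Delta * X^2, ">") ~ (nm^2)),
                  subtitle = sprintf("D = %.4f nm^2/ns", object$D)) +
    ggplot2::theme_minimal()
}

#' Plot a mobility fit
#'
#' Drift velocity against field with the through-origin fit line; the
#' slope is the electrophoretic mobility.
#'
#' @param object A `mobility_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mobility_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$E, .data$v)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = 0, slope = object$mu,
                         colour = "firebrick") +
    ggplot2::labs(x = "E (V/nm)", y = "v (nm/ns)",
                  subtitle = sprintf("mu = %.1f nm^2/(ns V)", object$mu)) +
    ggplot2::theme_minimal()
}
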