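# broom-style tidiers for the fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a persistence-length fit
#'
#' @param x A `persistence_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted quantity.
#' @export
tidy.persistence_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lp", "slope"),
    estimate = c(x$lp, x$slope),
    std.error = c(x$lp_stderr, x$slope_stderr)
  )
}

#' @rdname tidy.persistence_fit
#' @export
glance.persistence_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    lp = x$lp, lp_stderr = x$lp_stderr, spacing = x$spacing,
    r.squared = s$r.squared, n_points = length(s$residuals),
    fit_min = x$fit_range[1], fit_max = x$fit_range[2]
  )
}

#' Tidy a diffusion fit
#'
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = "D", estimate = x$D, std.error = x$D_stderr)
}

#' @rdname tidy.diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    D = x$D, D_stderr = x$D_stderr,
    window_min = x$fit_window[1], window_max = x$fit_window[2],
    r.squared = suppressWarnings(summary(x$fit))$r.squared
  )
}

#' Tidy a drift-velocity fit
#'
#' @param x A `drift_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.drift_fit <- function(x, ...) {
  tibble::tibble(term = "v", estimate = x$v, std.error = x$v_stderr)
}

#' Tidy a mobility fit
#'
#' @param x A `mobility_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mobility_fit <- function(x, ...) {
  tibble::tibble(term = "mu", estimate = x$mu, std.error = x$mu_stderr)
}

#' Tidy a transport summary
#'
#' @param x A `transport_fit`.
#' @param ... Unused.
#' @return A tibble with one row per transport quantity.
#' @export
tidy.transport_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "D", "q_eff", "screening", "manning"),
    estimate = c(x$mu, x$D, x$q_eff, x$screening, x$manning),
    unit = c("nm^2/(ns V)", "nm^2/ns", "e", "", "")
  )
}

#' @rdname tidy.transport_fit
#' @export
glance.transport_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, D = x$D, q_eff = x$q_eff,
    screening = x$screening, manning = x$manning,
    temperature = x$temperature,
    n_backbone_charges = x$n_backbone_charges
  )
}
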