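#' Smooth two-material surface indicator
#'
#' Returns the indicator s between 0 and 1 of how deep a point lies inside
#' material B (the strongly binding material): 0 deep inside material A,
#' 1 deep inside B.  `single_boundary` uses
#' \eqn{s(x) = \tfrac12[1 + \tanh(x/\delta)]}; `stripe` uses
#' \eqn{s(y) = \tfrac12[\tanh((y + w/2)/\delta) - \tanh((y - w/2)/\delta)]}
#' with the stripe along x centred on y = 0.  For `uniform` geometry the
#' indicator is identically zero (there is no second material).
#'
#' @param x,y Coordinates in nm (vectorised).
#' @param pattern A [surface_pattern()].
#' @return Numeric vector of indicator values in \[0, 1\].
#' @examples
#' pat <- surface_pattern("stripe")
#' surface_indicator(0, 0, pat)      # ~0.995 at the stripe centre
#' surface_indicator(0, 0.9, pat)    # ~0.5 at the stripe edge
#' @export
surface_indicator <- function(x, y, pattern) {
  stopifnot(inherits(pattern, "surface_pattern"))
  switch(pattern$geometry,
    uniform = rep(0, length(x)),
    single_boundary = 0.5 * (1 + tanh(x / pattern$smoothing)),
    stripe = {
      w2 <- pattern$stripe_width / 2
      d <- pattern$smoothing
      0.5 * (tanh((y + w2) / d) - tanh((y - w2) / d))
    }
  )
}

#' Potential energy of a chain configuration
#'
#' Evaluates the coarse-grained energy in kBT, broken into terms:
#' harmonic bonds \eqn{\sum \tfrac12 k_b(|r_{i+1}-r_i| - a)^2}; bending
#' \eqn{\sum \kappa(1-\cos\theta_i)} over interior joints; soft excluded
#' volume \eqn{\epsilon(1 - r/d)^2} for non-bonded pairs closer than d;
#' surface adhesion \eqn{\sum_i \Delta\epsilon\, s(r_i)} (only the
#' well-depth *contrast* enters — the uniform base depth exerts no force
#' and is dropped); and the field term \eqn{-\sum_i q_i E x_i}
#' converted to kBT through the thermal voltage.
#'
#' @param state Bead positions: an n x 2 matrix or data frame with
#'   columns `x`, `y` (nm).
#' @param params A [chain_params()].
#' @param pattern A [surface_pattern()]; default uniform.
#' @param field A [field_spec()]; default zero field.
#' @return A one-row tibble with columns `bond`, `bend`,
#'   `excluded_volume`, `surface`, `field`, `total` (kBT).
#' @examples
#' p <- chain_params()
#' st <- init_chain(p, "linear")
#' chain_energy(st, p)   # bond = bend = 0 for the straight rest chain
#' @export
chain_energy <- function(state, params,
                         pattern = surface_pattern("uniform"),
                         field = field_spec(0)) {
  stopifnot(inherits(params, "chain_params"),
            inherits(pattern, "surface_pattern"),
            inherits(field, "field_spec"))
  pos <- check_state(as_positions(state), params)
  n <- nrow(pos)

  bonds <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  blen <- sqrt(rowSums(bonds^2))
  if (any(blen <= 0)) stop("degenerate (zero-length) bond")
  e_bond <- 0.5 * params$bond_stiffness * sum((blen - params$bond_length)^2)

  e_bend <- 0
  if (n >= 3) {
    u <- bonds / blen
    cosang <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
    e_bend <- params$bend_stiffness * sum(1 - cosang)
  }

  e_ev <- 0
  if (params$excluded_volume && n >= 3) {
    d <- params$ev_diameter
    for (i in seq_len(n - 2)) {
      dx <- pos[(i + 2):n, 1] - pos[i, 1]
      dy <- pos[(i + 2):n, 2] - pos[i, 2]
      r2 <- dx * dx + dy * dy
      close <- r2 < d * d
      if (any(close)) {
        r <- sqrt(r2[close])
        e_ev <- e_ev + params$ev_strength * sum((1 - r / d)^2)
      }
    }
  }

  e_surf <- pattern$delta_eps * sum(surface_indicator(pos[, 1], pos[, 2], pattern))

  e_field <- 0
  if (field$E != 0) {
    e_field <- -sum(params$bead_charge * field$E * pos[, 1]) /
      thermal_voltage(params$temperature)
  }

  tibble::tibble(
    bond = e_bond, bend = e_bend, excluded_volume = e_ev,
    surface = e_surf, field = e_field,
    total = e_bond + e_bend + e_ev + e_surf + e_field
  )
}

#' Forces on each bead
#'
#' Analytic negative gradient of [chain_energy()] with respect to the
#' bead coordinates, including the sech-squared derivative of the tanh
#' surface profile.  Evaluated in compiled code; the same force routine
#' drives the Brownian-dynamics integrator.
#'
#' @inheritParams chain_energy
#' @return A tibble with columns `bead`, `fx`, `fy` (kBT/nm).
#' @examples
#' p <- chain_params()
#' chain_forces(init_chain(p, "linear"), p)  # all zero at the rest state
#' @export
chain_forces <- function(state, params,
                         pattern = surface_pattern("uniform"),
                         field = field_spec(0)) {
  stopifnot(inherits(params, "chain_params"),
            inherits(pattern, "surface_pattern"),
            inherits(field, "field_spec"))
  pos <- check_state(as_positions(state), params)
  f <- forces_cpp(pos, model_spec_cpp(params, pattern, field))
  tibble::tibble(bead = seq_len(nrow(pos)), fx = f[, 1], fy = f[, 2])
}

# Flatten params/pattern/field into the plain list the C++ core expects.
model_spec_cpp <- function(params, pattern, field) {
  geom <- match(pattern$geometry, c("uniform", "single_boundary", "stripe")) - 1L
  list(
    a = params$bond_length,
    k_bond = params$bond_stiffness,
    kappa = params$bend_stiffness,
    ev_on = as.integer(params$excluded_volume),
    ev_d = params$ev_diameter,
    ev_eps = params$ev_strength,
    geom = geom,
    delta_eps = pattern$delta_eps,
    w = pattern$stripe_width,
    smooth = pattern$smoothing,
    # per-bead field force in kBT/nm (charge q in e, E in V/nm)
    f_field = params$bead_charge * field$E / thermal_voltage(params$temperature),
    gamma = params$bead_friction
  )
}
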