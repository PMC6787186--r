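#' Coarse-grained chain parameters
#'
#' Defines the discrete worm-like chain standing in for a short
#' single-stranded DNA molecule adsorbed on a planar surface: `n_beads`
#' monomers connected by stiff harmonic bonds of rest length
#' `bond_length` with a bending energy \eqn{\kappa(1 - \cos\theta)} at
#' each interior joint.  By default the bending stiffness is derived
#' from the target persistence length through the exact 2D relation
#' \eqn{\langle\cos\theta\rangle = I_1(\kappa/k_BT)/I_0(\kappa/k_BT) =
#' e^{-a/l_p}} (see [bend_stiffness_from_lp()]).
#'
#' The soft excluded-volume repulsion is off by default: in two
#' dimensions self-avoidance gives a short chain distinctly
#' non-exponential tangent correlations, so a self-avoiding default
#' would make [fit_persistence_length()] read substantially more than
#' `target_lp` at any bending stiffness (see the methods vignette).
#' Enable it for scenarios whose initial conformations self-overlap.
#'
#' Defaults describe a 20-mer with monomer spacing 0.625 nm (contour
#' length 12.5 nm), target persistence length 1.39 nm, total effective
#' charge 10.2 e spread uniformly over the beads, and a per-bead friction
#' chosen so the free chain's centre-of-mass diffusion constant
#' \eqn{k_BT/(n\gamma)} equals 0.13 nm²/ns.
#'
#' @param n_beads Number of beads (monomers), at least 2.
#' @param bond_length Rest bond length a in nm.
#' @param target_lp Target persistence length in nm, used to derive
#'   `bend_stiffness` when the latter is `NULL`.
#' @param bond_stiffness Harmonic bond constant in kBT/nm²; default
#'   100 kBT/a².
#' @param bend_stiffness Bending constant kappa in kBT; default derived
#'   from `target_lp`.
#' @param excluded_volume Logical; include the soft repulsive pair term
#'   between non-bonded beads.
#' @param ev_diameter Excluded-volume diameter in nm (default `bond_length`).
#' @param ev_strength Height of the soft repulsion at full overlap, kBT.
#' @param bead_charge Charge per bead in units of e (default 10.2/20).
#' @param bead_friction Friction per bead in kBT·ns/nm²; default
#'   `1/(n_beads * chain_diffusion)`.
#' @param chain_diffusion Target chain centre-of-mass diffusion constant
#'   in nm²/ns used for the default friction.
#' @param temperature Working temperature in kelvin.
#' @return A list of class `chain_params`.
#' @examples
#' p <- chain_params()
#' p$n_beads * p$bond_length   # contour length, 12.5 nm
#' @export
chain_params <- function(n_beads = 20,
                         bond_length = 0.625,
                         target_lp = 1.39,
                         bond_stiffness = NULL,
                         bend_stiffness = NULL,
                         excluded_volume = FALSE,
                         ev_diameter = bond_length,
                         ev_strength = 1,
                         bead_charge = 10.2 / 20,
                         bead_friction = NULL,
                         chain_diffusion = 0.13,
                         temperature = 300) {
  stopifnot(n_beads >= 2, bond_length > 0, target_lp > 0,
            ev_diameter > 0, ev_strength >= 0, chain_diffusion > 0,
            temperature > 0)
  if (is.null(bond_stiffness)) bond_stiffness <- 100 / bond_length^2
  if (is.null(bend_stiffness)) {
    bend_stiffness <- bend_stiffness_from_lp(target_lp, bond_length)
  }
  if (is.null(bead_friction)) bead_friction <- 1 / (n_beads * chain_diffusion)
  stopifnot(bond_stiffness > 0, bend_stiffness >= 0, bead_friction > 0)
  structure(
    list(
      n_beads = as.integer(n_beads),
      bond_length = bond_length,
      target_lp = target_lp,
      bond_stiffness = bond_stiffness,
      bend_stiffness = bend_stiffness,
      excluded_volume = isTRUE(excluded_volume),
      ev_diameter = ev_diameter,
      ev_strength = ev_strength,
      bead_charge = bead_charge,
      bead_friction = bead_friction,
      temperature = temperature
    ),
    class = "chain_params"
  )
}

#' Bending stiffness from a target persistence length (2D chain)
#'
#' For a discrete chain in two dimensions with joint energy
#' \eqn{\kappa(1-\cos\theta)}, the equilibrium tangent correlation per
#' joint is the Bessel ratio \eqn{\langle\cos\theta\rangle =
#' I_1(\beta\kappa)/I_0(\beta\kappa)}.  Matching a worm-like-chain decay
#' \eqn{e^{-a/l_p}} fixes \eqn{\kappa}; this function inverts the Bessel
#' ratio numerically.  The large-\eqn{\kappa} asymptote
#' \eqn{\kappa \approx l_p k_BT/(2a)} is a poor approximation at
#' moderate stiffness (a/lp near 0.5), hence the exact inversion.
#'
#' @param lp Target persistence length, nm.
#' @param a Bond length, nm.
#' @return Bending constant kappa in kBT.
#' @examples
#' bend_stiffness_from_lp(1.39, 0.625)  # ~1.69 kBT
#' @export
bend_stiffness_from_lp <- function(lp, a) {
  stopifnot(lp > 0, a > 0)
  target <- exp(-a / lp)
  f <- function(x) bessel_ratio(x) - target
  stats::uniroot(f, lower = 1e-8, upper = 1e4, tol = 1e-12)$root
}

#' @rdname bend_stiffness_from_lp
#' @param kappa Bending constant in kBT.
#' @return `lp_from_bend_stiffness()`: the persistence length implied by
#'   `kappa` for bond length `a`.
#' @export
lp_from_bend_stiffness <- function(kappa, a) {
  stopifnot(kappa > 0, a > 0)
  -a / log(bessel_ratio(kappa))
}

# I1(x)/I0(x), numerically stable via exponential scaling
bessel_ratio <- function(x) {
  besselI(x, 1, expon.scaled = TRUE) / besselI(x, 0, expon.scaled = TRUE)
}

#' Patterned-surface adhesion landscape
#'
#' Describes a flat two-material surface on which every bead feels a
#' binding energy that is deeper on material B by `delta_eps` (negative
#' by convention).  Geometries: `"uniform"` (no lateral contrast),
#' `"single_boundary"` (material B occupies x > 0) and `"stripe"`
#' (material B is a stripe of width `stripe_width` along x, centred on
#' y = 0).  The boundary is smoothed over `smoothing` nm with a tanh
#' profile so forces are analytic.  The common base well depth
#' (`base_eps_kcal`, e.g. about -23.2 kcal/mol per monomer on graphene)
#' exerts no lateral force and is kept as metadata only; desorption off
#' the surface is not modelled.
#'
#' @param geometry One of `"uniform"`, `"single_boundary"`, `"stripe"`.
#' @param delta_eps_kcal Extra binding on material B, kcal/mol per bead
#'   (negative = deeper).  Default -6.1.
#' @param base_eps_kcal Base well depth on material A, kcal/mol per bead
#'   (metadata).
#' @param stripe_width Stripe width w in nm.
#' @param smoothing Boundary smoothing length delta in nm.
#' @param temperature Temperature used for the kcal/mol to kBT conversion.
#' @return A list of class `surface_pattern`; `delta_eps` holds the
#'   contrast converted to kBT.
#' @examples
#' surface_pattern("stripe")
#' @export
surface_pattern <- function(geometry = c("uniform", "single_boundary", "stripe"),
                            delta_eps_kcal = -6.1,
                            base_eps_kcal = -23.2,
                            stripe_width = 1.8,
                            smoothing = 0.3,
                            temperature = 300) {
  geometry <- match.arg(geometry)
  stopifnot(stripe_width > 0, smoothing > 0)
  if (geometry != "uniform" && delta_eps_kcal >= 0) {
    stop("`delta_eps_kcal` must be negative: material B binds more strongly")
  }
  structure(
    list(
      geometry = geometry,
      delta_eps = kcal_to_kbt(delta_eps_kcal, temperature),
      delta_eps_kcal = delta_eps_kcal,
      base_eps_kcal = base_eps_kcal,
      stripe_width = stripe_width,
      smoothing = smoothing
    ),
    class = "surface_pattern"
  )
}

#' In-plane electric field specification
#'
#' The driving field acts along +x.  Give either the field directly in
#' V/nm, or a biasing voltage together with the box length along x so
#' that E = V/Lx.
#'
#' @param E Field strength, V/nm.
#' @param voltage Biasing voltage in volts (alternative to `E`).
#' @param box_length Box length Lx in nm (required with `voltage`).
#' @return A list of class `field_spec` with elements `E`, and `voltage`,
#'   `box_length` when supplied.
#' @examples
#' field_spec(E = 0.005)
#' field_spec(voltage = 0.2, box_length = 40)
#' @export
field_spec <- function(E = 0, voltage = NULL, box_length = NULL) {
  if (!is.null(voltage)) {
    if (is.null(box_length) || box_length <= 0) {
      stop("`box_length` (> 0) is required when `voltage` is given")
    }
    E_from_v <- voltage / box_length
    if (!missing(E) && abs(E - E_from_v) > 1e-12 * max(1, abs(E))) {
      stop("inconsistent field: E != voltage/box_length")
    }
    E <- E_from_v
  }
  stopifnot(is.numeric(E), length(E) == 1L, is.finite(E))
  structure(
    list(E = E, voltage = voltage, box_length = box_length),
    class = "field_spec"
  )
}

#' @export
print.chain_params <- function(x, ...) {
  cat("<chain_params>", x$n_beads, "beads; a =", x$bond_length, "nm;",
      "lc =", x$n_beads * x$bond_length, "nm\n")
  cat("  kappa =", format(x$bend_stiffness, digits = 4),
      "kBT (target lp", x$target_lp, "nm);",
      "k_bond =", format(x$bond_stiffness, digits = 4), "kBT/nm2\n")
  cat("  charge/bead =", format(x$bead_charge, digits = 4), "e;",
      "friction/bead =", format(x$bead_friction, digits = 4), "kBT ns/nm2;",
      "excluded volume:", if (x$excluded_volume) "on" else "off", "\n")
  invisible(x)
}

#' @export
print.surface_pattern <- function(x, ...) {
  cat("<surface_pattern>", x$geometry)
  if (x$geometry != "uniform") {
    cat("; delta_eps =", format(x$delta_eps, digits = 4), "kBT (",
        x$delta_eps_kcal, "kcal/mol )")
    if (x$geometry == "stripe") cat("; w =", x$stripe_width, "nm")
    cat("; smoothing =", x$smoothing, "nm")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.field_spec <- function(x, ...) {
  cat("<field_spec> E =", x$E, "V/nm along +x\n")
  invisible(x)
}

# Coerce bead positions to an n x 2 numeric matrix (internal)
as_positions <- function(state) {
  if (is.matrix(state)) {
    stopifnot(ncol(state) >= 2)
    pos <- state[, 1:2, drop = FALSE]
  } else if (is.data.frame(state)) {
    stopifnot(all(c("x", "y") %in% names(state)))
    pos <- cbind(state$x, state$y)
  } else {
    stop("bead positions must be a matrix or a data frame with x, y columns")
  }
  storage.mode(pos) <- "double"
  if (!all(is.finite(pos))) stop("non-finite bead coordinates")
  pos
}

check_state <- function(pos, params) {
  if (nrow(pos) != params$n_beads) {
    stop("state has ", nrow(pos), " beads but params expect ",
         params$n_beads)
  }
  invisible(pos)
}
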