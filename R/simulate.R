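#' Build an initial chain configuration
#'
#' @param params A [chain_params()].
#' @param conformation `"linear"` (beads colinear along x at the rest
#'   spacing), `"circular"` (beads on a ring of circumference n·a) or
#'   `"random_walk"` (freely jointed 2D walk at spacing a; transient
#'   self-overlaps are relaxed by the excluded-volume repulsion during
#'   equilibration).
#' @param offset Length-2 numeric: translation applied to the chain
#'   centre of mass, nm.  Used to place a chain relative to a boundary
#'   or stripe.
#' @param rng_seed Optional seed for the random walk; `NULL` uses the
#'   current RNG state.
#' @return A tibble with columns `bead`, `x`, `y` (nm), centred on
#'   `offset`.
#' @examples
#' init_chain(chain_params(), "circular")
#' @export
init_chain <- function(params,
                       conformation = c("linear", "circular", "random_walk"),
                       offset = c(0, 0), rng_seed = NULL) {
  stopifnot(inherits(params, "chain_params"), length(offset) == 2)
  conformation <- match.arg(conformation)
  n <- params$n_beads
  a <- params$bond_length
  if (!is.null(rng_seed)) set.seed(rng_seed)
  pos <- switch(conformation,
    linear = cbind(a * (seq_len(n) - 1), rep(0, n)),
    circular = {
      r <- n * a / (2 * pi)
      th <- 2 * pi * (seq_len(n) - 1) / n
      cbind(r * cos(th), r * sin(th))
    },
    random_walk = {
      th <- stats::runif(n - 1, 0, 2 * pi)
      cbind(cumsum(c(0, a * cos(th))), cumsum(c(0, a * sin(th))))
    }
  )
  pos <- sweep(pos, 2, colMeans(pos))          # centre on origin
  pos <- sweep(pos, 2, offset, `+`)
  tibble::tibble(bead = seq_len(n), x = pos[, 1], y = pos[, 2])
}

#' Maximum stable Brownian-dynamics time step
#'
#' Bond relaxation limits the explicit Euler–Maruyama step:
#' dt <= 0.1 gamma / k_bond.  With default parameters this is about
#' 1.5e-4 ns, which is the package default `dt`.
#'
#' @param params A [chain_params()].
#' @return Maximum dt in ns.
#' @export
bd_max_dt <- function(params) {
  0.1 * params$bead_friction / params$bond_stiffness
}

#' Run overdamped Langevin (Brownian) dynamics
#'
#' Integrates \eqn{\Delta r_i = F_i\,dt/\gamma + \sqrt{2 k_BT\,dt/\gamma}\,\xi}
#' (Euler–Maruyama, no hydrodynamic interactions) for a chain on the
#' given surface pattern and field, sampling every `sample_every` steps.
#' Coordinates are evolved unwrapped; when `box_length` is supplied a
#' wrapped `x_wrapped` column is added for visualisation.
#'
#' @param params A [chain_params()].
#' @param init Initial bead positions (from [init_chain()] or any
#'   two-column state).
#' @param pattern A [surface_pattern()].
#' @param field A [field_spec()].
#' @param n_steps Number of integration steps.
#' @param dt Time step in ns; default [bd_max_dt()] of `params`
#'   (rounded down slightly).  Must satisfy the stability criterion.
#' @param sample_every Store every this-many steps.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param discard_frac Fraction of the run (from the start) dropped as
#'   equilibration before frames are returned.
#' @param box_length Optional box length along x (nm) used only to add a
#'   wrapped coordinate column.
#' @param scenario_name Free-form label stored in the provenance.
#' @return A `bd_trajectory`: a tibble with columns `frame`, `time`,
#'   `bead`, `x`, `y` (and `x_wrapped` if `box_length` given), carrying
#'   the full provenance (params, pattern, field, dt, seed, ...) as
#'   attributes.
#' @examples
#' p <- chain_params(n_beads = 5)
#' tr <- bd_simulate(p, init_chain(p, "linear"), n_steps = 2000, seed = 1)
#' @export
bd_simulate <- function(params, init,
                        pattern = surface_pattern("uniform"),
                        field = field_spec(0),
                        n_steps = 1e7,
                        dt = NULL,
                        sample_every = 1000,
                        seed = NULL,
                        discard_frac = 0,
                        box_length = NULL,
                        scenario_name = "custom") {
  stopifnot(inherits(params, "chain_params"))
  if (is.null(dt)) dt <- signif(bd_max_dt(params), 2)
  if (dt > bd_max_dt(params) * (1 + 1e-9)) {
    stop("dt = ", dt, " ns violates the stability criterion dt <= 0.1*gamma/k_bond = ",
         signif(bd_max_dt(params), 3), " ns")
  }
  stopifnot(discard_frac >= 0, discard_frac < 1)
  pos0 <- check_state(as_positions(init), params)
  if (!is.null(seed)) set.seed(seed)
  spec <- model_spec_cpp(params, pattern, field)
  res <- bd_run_cpp(pos0, spec, dt, as.integer(n_steps),
                    as.integer(sample_every))
  frames <- res$frames                       # n_beads x 2 x n_frames
  n <- params$n_beads
  nf <- length(res$times)
  keep <- which(res$times >= discard_frac * n_steps * dt)
  traj <- tibble::tibble(
    frame = rep(seq_along(keep), each = n),
    time = rep(res$times[keep], each = n),
    bead = rep(seq_len(n), times = length(keep)),
    x = as.vector(frames[, 1, keep]),
    y = as.vector(frames[, 2, keep])
  )
  if (!is.null(box_length)) {
    traj$x_wrapped <- traj$x %% box_length
  }
  new_bd_trajectory(traj,
    params = params, pattern = pattern, field = field,
    dt = dt, sample_every = sample_every, n_steps = n_steps,
    seed = seed, discard_frac = discard_frac,
    scenario = scenario_name, n_frames_total = nf
  )
}

new_bd_trajectory <- function(tbl, ...) {
  prov <- list(...)
  attr(tbl, "provenance") <- prov
  class(tbl) <- c("bd_trajectory", class(tbl))
  tbl
}

#' Trajectory provenance
#'
#' @param traj A `bd_trajectory`.
#' @return The provenance list (params, pattern, field, dt, seed, ...).
#' @export
trajectory_provenance <- function(traj) {
  attr(traj, "provenance")
}

n_beads_of <- function(traj) {
  prov <- trajectory_provenance(traj)
  if (!is.null(prov$params)) prov$params$n_beads else max(traj$bead)
}

frame_dt <- function(traj) {
  tt <- unique(traj$time)
  if (length(tt) < 2) stop("trajectory has fewer than 2 frames")
  dts <- diff(tt)
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stop("frames are not uniformly spaced in time")
  }
  dts[1]
}

#' Scenario presets for the synthetic-data generator
#'
#' Bundles chain, surface, field and run-length choices into the four
#' study conditions the analysis pipeline expects:
#'
#' * `free_uniform` — free chain on a uniform surface (persistence-length
#'   and free-diffusion statistics); mirrors runs on a single material.
#' * `boundary_crossing` — chain released 2 nm inside the weakly binding
#'   material next to a single boundary; with a ~10 kBT/bead contrast the
#'   chain crosses onto the strong material and does not return.
#' * `stripe_confinement` — chain placed along a 1.8-nm deep-binding
#'   stripe; measures confinement-induced stretching.
#' * `driven_transport` — stripe plus an in-plane field along the stripe;
#'   measures drift, mobility and (at zero field) 1D diffusion.
#'
#' When `params` is left at its default, the confinement and transport
#' presets enable the soft excluded-volume repulsion: a chain pressed
#' into a stripe can otherwise lower its extension by folding through
#' itself, which is unphysical.  The free-surface presets use the ideal
#' chain, whose tangent statistics are exactly the worm-like-chain form
#' the persistence-length estimator assumes (see the methods vignette
#' for why both choices matter).  Passing `params` or `excluded_volume`
#' explicitly overrides the preset.
#'
#' @param name Scenario name (see above).
#' @param params A [chain_params()]; defaults to the standard 20-mer
#'   with the preset's excluded-volume setting.
#' @param excluded_volume Logical override for the preset's
#'   excluded-volume default (ignored when `params` is supplied).
#' @param field_E Field strength in V/nm (driven_transport only).
#' @param initial_conformation Overrides the preset initial conformation.
#' @param offset Overrides the preset chain placement (nm).
#' @param n_steps,dt,sample_every,discard_frac Run-length controls; the
#'   defaults are the production settings (1e7 steps of 1.5e-4 ns,
#'   sampled every 1000 steps, first 10% discarded).
#' @param seed Integer seed.
#' @return A list of class `bd_scenario`; pass to [run_scenario()].
#' @examples
#' sc <- scenario("stripe_confinement", n_steps = 1e4, seed = 1)
#' tr <- run_scenario(sc)
#' @export
scenario <- function(name = c("free_uniform", "boundary_crossing",
                              "stripe_confinement", "driven_transport"),
                     params = NULL,
                     excluded_volume = NULL,
                     field_E = 0.005,
                     initial_conformation = NULL,
                     offset = NULL,
                     n_steps = 1e7,
                     dt = NULL,
                     sample_every = 1000,
                     discard_frac = 0.1,
                     seed = 1) {
  name <- match.arg(name)
  if (is.null(params)) {
    ev <- if (!is.null(excluded_volume)) {
      isTRUE(excluded_volume)
    } else {
      name %in% c("stripe_confinement", "driven_transport")
    }
    params <- chain_params(excluded_volume = ev)
  }
  preset <- switch(name,
    free_uniform = list(
      pattern = surface_pattern("uniform"),
      field = field_spec(0),
      conformation = "linear", offset = c(0, 0)
    ),
    boundary_crossing = list(
      pattern = surface_pattern("single_boundary"),
      field = field_spec(0),
      conformation = "random_walk", offset = c(-2, 0)
    ),
    stripe_confinement = list(
      pattern = surface_pattern("stripe"),
      field = field_spec(0),
      conformation = "linear", offset = c(0, 0)
    ),
    driven_transport = list(
      pattern = surface_pattern("stripe"),
      field = field_spec(E = field_E),
      conformation = "linear", offset = c(0, 0)
    )
  )
  if (!is.null(initial_conformation)) preset$conformation <- initial_conformation
  if (!is.null(offset)) preset$offset <- offset
  structure(
    list(
      name = name, params = params, pattern = preset$pattern,
      field = preset$field, conformation = preset$conformation,
      offset = preset$offset, n_steps = n_steps, dt = dt,
      sample_every = sample_every, discard_frac = discard_frac,
      seed = as.integer(seed)
    ),
    class = "bd_scenario"
  )
}

#' Run a scenario preset
#'
#' Seeds the RNG, builds the initial conformation, integrates, discards
#' the equilibration segment, and returns the sampled trajectory with
#' full provenance.  Identical scenario + seed gives a bit-identical
#' trajectory.
#'
#' @param sc A [scenario()].
#' @param quiet Suppress the one-line run summary on stderr.
#' @return A `bd_trajectory`.
#' @export
run_scenario <- function(sc, quiet = TRUE) {
  stopifnot(inherits(sc, "bd_scenario"))
  set.seed(sc$seed)
  init <- init_chain(sc$params, sc$conformation, offset = sc$offset)
  traj <- bd_simulate(
    sc$params, init,
    pattern = sc$pattern, field = sc$field,
    n_steps = sc$n_steps, dt = sc$dt, sample_every = sc$sample_every,
    seed = NULL,                       # RNG already seeded above
    discard_frac = sc$discard_frac,
    scenario_name = sc$name
  )
  prov <- attr(traj, "provenance")
  prov$seed <- sc$seed
  prov$conformation <- sc$conformation
  prov$offset <- sc$offset
  attr(traj, "provenance") <- prov
  if (!quiet) {
    ee <- end_to_end(traj)
    message(sprintf(
      "[%s] seed=%d steps=%g dt=%g ns frames=%d  <end-to-end>=%.2f nm",
      sc$name, sc$seed, sc$n_steps, prov$dt,
      dplyr::n_distinct(traj$frame), mean(ee$r_ee)))
  }
  traj
}

#' @export
print.bd_scenario <- function(x, ...) {
  cat("<bd_scenario>", x$name, "| seed", x$seed, "|",
      format(x$n_steps, big.mark = ","), "steps, sample_every",
      x$sample_every, "\n")
  invisible(x)
}

#' @export
print.bd_trajectory <- function(x, ...) {
  prov <- trajectory_provenance(x)
  cat("<bd_trajectory>", if (!is.null(prov$scenario)) prov$scenario else "",
      "|", dplyr::n_distinct(x$frame), "frames x",
      dplyr::n_distinct(x$bead), "beads | dt_frame =",
      format(frame_dt(x), digits = 4), "ns\n")
  NextMethod()
}
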