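# Trajectory estimators: conformational observables, worm-like-chain
# persistence-length fit, MSD/diffusion, drift/mobility, effective
# charge, screening, Manning condensation, occupancy and proximity.

# frames x beads coordinate matrices, frame-major and bead-sorted
traj_matrices <- function(traj) {
  stopifnot(all(c("frame", "bead", "x", "y") %in% names(traj)))
  tr <- dplyr::arrange(traj, .data$frame, .data$bead)
  nb <- dplyr::n_distinct(tr$bead)
  nf <- nrow(tr) / nb
  if (nf != round(nf)) stop("trajectory is ragged: bead count varies by frame")
  list(
    X = matrix(tr$x, nrow = nf, ncol = nb, byrow = TRUE),
    Y = matrix(tr$y, nrow = nf, ncol = nb, byrow = TRUE),
    time = matrix(tr$time, nrow = nf, ncol = nb, byrow = TRUE)[, 1],
    n_frames = nf, n_beads = nb
  )
}

#' End-to-end distance per frame
#'
#' Euclidean distance between the first and last bead.
#'
#' @param traj A trajectory tibble (columns `frame`, `time`, `bead`,
#'   `x`, `y`); a single-frame state works too.
#' @return A tibble with columns `frame`, `time`, `r_ee` (nm).
#' @examples
#' p <- chain_params()
#' end_to_end(cbind(init_chain(p, "linear"), frame = 1, time = 0))
#' @export
end_to_end <- function(traj) {
  m <- traj_matrices(as_traj_tbl(traj))
  if (m$n_beads < 2) stop("end-to-end distance needs at least 2 beads")
  tibble::tibble(
    frame = seq_len(m$n_frames),
    time = m$time,
    r_ee = sqrt((m$X[, m$n_beads] - m$X[, 1])^2 +
                (m$Y[, m$n_beads] - m$Y[, 1])^2)
  )
}

# accept a bare state (no frame/time columns) as a 1-frame trajectory
as_traj_tbl <- function(traj) {
  traj <- tibble::as_tibble(traj)
  if (!"bead" %in% names(traj)) traj$bead <- seq_len(nrow(traj))
  if (!"frame" %in% names(traj)) traj$frame <- 1L
  if (!"time" %in% names(traj)) traj$time <- 0
  traj
}

#' Mean neighbour spacing
#'
#' Average bond length over all neighbouring bead pairs and frames:
#' the effective monomer spacing a entering the worm-like-chain fit.
#'
#' @inheritParams end_to_end
#' @return Mean spacing in nm.
#' @export
mean_spacing <- function(traj) {
  m <- traj_matrices(as_traj_tbl(traj))
  nb <- m$n_beads
  mean(sqrt(diff(t(m$X))^2 + diff(t(m$Y))^2))
}

#' Tangent-vector correlation along the chain
#'
#' Unit tangents t_i along each bond; the correlation
#' C(N) = <t_i . t_{i+N}> is averaged over all valid bead indices i and
#' over frames.  For a worm-like chain C(N) decays as
#' exp(-N a / lp), which [fit_persistence_length()] exploits.
#'
#' @inheritParams end_to_end
#' @param max_sep Largest tangent separation N (bonds); at most
#'   `n_beads - 2`.
#' @return A tibble with columns `separation` (N = 1..max_sep),
#'   `correlation`, `n_pairs`.
#' @export
tangent_correlation <- function(traj, max_sep = NULL) {
  m <- traj_matrices(as_traj_tbl(traj))
  nb <- m$n_beads
  if (nb < 3) stop("need at least 3 beads for tangent correlations")
  if (is.null(max_sep)) max_sep <- nb - 2L
  stopifnot(max_sep >= 1, max_sep <= nb - 2L)
  TX <- t(diff(t(m$X)))                 # frames x (nb-1) bond vectors
  TY <- t(diff(t(m$Y)))
  L <- sqrt(TX^2 + TY^2)
  bad <- L <= 0
  if (any(bad)) {
    warning(sum(bad), " degenerate zero-length bonds excluded")
    L[bad] <- NA_real_
  }
  TX <- TX / L
  TY <- TY / L
  nbnd <- nb - 1L
  out <- lapply(seq_len(max_sep), function(N) {
    i <- seq_len(nbnd - N)
    d <- TX[, i, drop = FALSE] * TX[, i + N, drop = FALSE] +
         TY[, i, drop = FALSE] * TY[, i + N, drop = FALSE]
    tibble::tibble(separation = N,
                   correlation = mean(d, na.rm = TRUE),
                   n_pairs = sum(is.finite(d)))
  })
  dplyr::bind_rows(out)
}

#' Fit the persistence length from tangent correlations
#'
#' Least-squares fit of ln C(N) against the contour separation N·a;
#' the persistence length is lp = -1/slope.  Non-positive correlations
#' inside the fit range are dropped with a warning (they carry no
#' information for the log-linear fit).
#'
#' @param correlations Output of [tangent_correlation()] (columns
#'   `separation`, `correlation`), or a trajectory tibble, in which case
#'   correlations and the mean spacing are computed first.
#' @param spacing Monomer spacing a in nm.  Taken from the trajectory
#'   via [mean_spacing()] when `correlations` is a trajectory.
#' @param fit_range Integer range `c(N_min, N_max)` of separations used
#'   in the fit.  Default 1..6: for a 20-mer, larger separations are
#'   noise-dominated.
#' @return An object of class `persistence_fit` with elements `lp` (nm),
#'   `spacing`, `slope`, `slope_stderr`, `lp_stderr`, `fit_range`,
#'   `correlations` and the underlying `lm` fit.  Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @examples
#' corr <- tibble::tibble(separation = 1:6,
#'                        correlation = exp(-(1:6) * 0.625 / 1.39))
#' fit_persistence_length(corr, spacing = 0.625)$lp   # 1.39
#' @export
fit_persistence_length <- function(correlations, spacing = NULL,
                                   fit_range = c(1, 6)) {
  if (!is.null(correlations[["bead"]]) || !is.null(correlations[["x"]])) {
    traj <- correlations
    if (is.null(spacing)) spacing <- mean_spacing(traj)
    correlations <- tangent_correlation(traj)
  }
  stopifnot(!is.null(spacing), spacing > 0,
            all(c("separation", "correlation") %in% names(correlations)))
  fit_range <- as.integer(fit_range)
  d <- dplyr::filter(correlations,
                     .data$separation >= fit_range[1],
                     .data$separation <= fit_range[2])
  pos <- d$correlation > 0
  if (!all(pos)) {
    warning(sum(!pos), " non-positive correlation value(s) dropped from fit range")
    d <- d[pos, , drop = FALSE]
  }
  if (nrow(d) < 2) stop("fewer than 2 usable correlation points in fit range")
  fit <- stats::lm(log(correlation) ~ I(separation * spacing), data = d)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("non-decaying correlations: fitted slope >= 0")
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  lp <- -1 / slope
  structure(
    list(
      lp = lp,
      spacing = spacing,
      slope = slope,
      slope_stderr = se,
      lp_stderr = se / slope^2,     # delta method on lp = -1/slope
      fit_range = fit_range,
      correlations = correlations,
      fit = fit
    ),
    class = "persistence_fit"
  )
}

#' Centre-of-mass coordinate time series
#'
#' Per-frame mean of the chosen (unwrapped) coordinate over beads —
#' the displacement signal X(t) used for drift and MSD analysis.
#'
#' @inheritParams end_to_end
#' @param axis `"x"` or `"y"`.
#' @return A tibble with columns `time` (ns), `com` (nm).
#' @export
com_series <- function(traj, axis = c("x", "y")) {
  axis <- match.arg(axis)
  m <- traj_matrices(as_traj_tbl(traj))
  M <- if (axis == "x") m$X else m$Y
  tibble::tibble(time = m$time, com = rowMeans(M))
}

#' Windowed mean-squared displacement
#'
#' All-pairs (sliding-window) average of (X(t + dt) - X(t))^2 for each
#' lag, for a uniformly sampled scalar series.
#'
#' @param series A tibble with columns `time` and a value column (`com`
#'   or the first non-time column), or a plain numeric vector with
#'   `dt` supplied.
#' @param max_lag Largest lag in ns (default: a quarter of the series
#'   duration).
#' @param dt Sampling interval in ns (only for a bare numeric series).
#' @return A tibble with columns `lag` (ns), `msd` (nm^2), `n_pairs`.
#' @export
msd <- function(series, max_lag = NULL, dt = NULL) {
  if (is.numeric(series) && is.null(dim(series))) {
    stopifnot(!is.null(dt), dt > 0)
    xv <- series
  } else {
    stopifnot("time" %in% names(series))
    tt <- series$time
    dts <- diff(tt)
    if (length(dts) < 1) stop("series needs at least 2 points")
    if (max(dts) - min(dts) > 1e-9 * max(abs(dts))) {
      stop("series is not uniformly sampled")
    }
    dt <- dts[1]
    val_col <- setdiff(names(series), "time")[1]
    xv <- series[[val_col]]
  }
  n <- length(xv)
  if (is.null(max_lag)) max_lag <- (n - 1) * dt / 4
  max_k <- min(n - 1, floor(max_lag / dt + 1e-9))
  stopifnot(max_k >= 1)
  out <- vapply(seq_len(max_k), function(k) {
    d <- xv[(1 + k):n] - xv[1:(n - k)]
    c(mean(d * d), n - k)
  }, numeric(2))
  tibble::tibble(lag = seq_len(max_k) * dt, msd = out[1, ],
                 n_pairs = as.integer(out[2, ]))
}

#' 1D diffusion constant from an MSD curve
#'
#' Least-squares slope of MSD versus lag over a fit window, divided by
#' two (one-dimensional convention, free intercept):
#' D = <dX^2> / (2 dt).
#'
#' @param msd_curve Output of [msd()] (columns `lag`, `msd`).
#' @param fit_window Numeric `c(min_lag, max_lag)` in ns.  Default: the
#'   upper 20%–100% of the computed lags, which corresponds to lags of
#'   5%–25% of the series duration when `msd()` was run with its default
#'   quarter-duration `max_lag` (the standard bias/variance compromise).
#' @return An object of class `diffusion_fit` with `D` (nm^2/ns),
#'   `D_stderr`, `fit_window`, the `msd` curve and the `lm` fit.
#' @examples
#' curve <- tibble::tibble(lag = 1:10, msd = 2 * 0.13 * (1:10))
#' fit_diffusion(curve, fit_window = c(1, 10))$D   # 0.13
#' @export
fit_diffusion <- function(msd_curve, fit_window = NULL) {
  stopifnot(all(c("lag", "msd") %in% names(msd_curve)))
  lag_max <- max(msd_curve$lag)
  if (is.null(fit_window)) fit_window <- c(0.2, 1.0) * lag_max
  d <- dplyr::filter(msd_curve, .data$lag >= fit_window[1],
                     .data$lag <= fit_window[2])
  if (nrow(d) < 2) stop("fewer than 2 MSD points in fit window")
  fit <- stats::lm(msd ~ lag, data = d)
  slope <- unname(stats::coef(fit)[2])
  if (slope < 0) {
    stop("negative MSD slope (", signif(slope, 3),
         " nm^2/ns) in window [", fit_window[1], ", ", fit_window[2], "] ns")
  }
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  structure(
    list(D = slope / 2, D_stderr = se / 2, fit_window = fit_window,
         msd = msd_curve, fit = fit),
    class = "diffusion_fit"
  )
}

#' Centre-of-mass diffusion constant of a chain
#'
#' Convenience pipeline `com_series() |> msd() |> fit_diffusion()` with a
#' small-lag fit window.  The centre of mass of a free (or
#' stripe-guided, zero-field) chain performs ideal Brownian motion along
#' x at all lag times, so the MSD slope is unbiased at any lag; fitting
#' over small lags (default: lags up to 1% of the run duration) uses the
#' many effectively independent displacement windows available there and
#' keeps the estimator's sampling spread to roughly
#' sqrt(4 tau_max / (3 T)), about 15–20% per production run.  At large
#' lag fractions (say a quarter of the run) the spread approaches the
#' estimate itself, which is why long-lag windows are left to
#' [fit_diffusion()]'s explicit `fit_window`.  Averaging the estimate
#' over a few independently seeded replicate runs is the intended usage
#' for quantitative work.
#'
#' @inheritParams end_to_end
#' @param axis Coordinate analysed (default `"x"`, the transport axis).
#' @param max_lag_frac Largest MSD lag as a fraction of the run
#'   duration.
#' @param window_frac Fit window as fractions of the largest lag.
#' @return A `diffusion_fit`.
#' @export
com_diffusion <- function(traj, axis = "x", max_lag_frac = 0.01,
                          window_frac = c(0.2, 1)) {
  series <- com_series(traj, axis)
  duration <- max(series$time) - min(series$time)
  ml <- max(max_lag_frac * duration, 2 * frame_dt(traj))
  fit_diffusion(msd(series, max_lag = ml), fit_window = window_frac * ml)
}

#' Drift velocity from a displacement series
#'
#' Least-squares slope of X(t): the mean velocity of a chain moving at
#' nearly constant speed under a field.
#'
#' @param series A tibble with columns `time` and a value column.
#' @return An object of class `drift_fit` with `v` (nm/ns), `v_stderr`
#'   and the `lm` fit.
#' @export
drift_velocity <- function(series) {
  stopifnot("time" %in% names(series), nrow(series) >= 2)
  val_col <- setdiff(names(series), "time")[1]
  d <- data.frame(time = series$time, xval = series[[val_col]])
  fit <- stats::lm(xval ~ time, data = d)
  structure(
    list(v = unname(stats::coef(fit)[2]),
         v_stderr = suppressWarnings(summary(fit))$coefficients[2, 2],
         fit = fit),
    class = "drift_fit"
  )
}

#' Electrophoretic mobility from velocity–field pairs
#'
#' Through-origin least-squares slope of drift velocity versus field
#' (v = 0 at E = 0 by symmetry), equivalent to mu = v Lx / V for a
#' voltage V over a box of length Lx.
#'
#' @param velocities A tibble/data frame with columns `E` (V/nm) and `v`
#'   (nm/ns); at least one nonzero-field point.
#' @return An object of class `mobility_fit` with `mu` (nm^2/(ns V)),
#'   `mu_stderr`, the data and the `lm` fit.
#' @examples
#' fit_mobility(tibble::tibble(E = 0.01, v = 0.516))$mu   # 51.6
#' @export
fit_mobility <- function(velocities) {
  stopifnot(all(c("E", "v") %in% names(velocities)))
  d <- tibble::as_tibble(velocities)
  if (!any(d$E != 0)) stop("need at least one nonzero-field point")
  fit <- stats::lm(v ~ 0 + E, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(mu = unname(stats::coef(fit)[1]),
         mu_stderr = if (nrow(d) > 1) sm[1, 2] else NA_real_,
         data = d, fit = fit),
    class = "mobility_fit"
  )
}

#' Einstein-relation effective charge
#'
#' q_eff = kBT mu / D expressed in elementary charges: mobility in
#' nm^2/(ns V), diffusion in nm^2/ns, and kBT/e the thermal voltage at
#' `temperature`.
#'
#' @param mu Electrophoretic mobility, nm^2/(ns V) (or a
#'   `mobility_fit`).
#' @param D Diffusion constant, nm^2/ns (or a `diffusion_fit`).
#' @param temperature Temperature in kelvin.
#' @return Effective charge in units of e.
#' @examples
#' effective_charge(51.6, 0.13)   # ~10.3 e
#' @export
effective_charge <- function(mu, D, temperature = 300) {
  if (inherits(mu, "mobility_fit")) mu <- mu$mu
  if (inherits(D, "diffusion_fit")) D <- D$D
  stopifnot(D > 0)
  thermal_voltage(temperature) * mu / D
}

#' Charge-screening fraction
#'
#' Fraction of the bare backbone charge not visible in the effective
#' charge: 1 - q_eff / n_backbone_charges.  A 20-mer backbone carries
#' 19 phosphate charges, the default.
#'
#' @param q_eff Effective charge in e.
#' @param n_backbone_charges Number of bare backbone charges.
#' @return Screening fraction in \[0, 1\] (negative values are clamped
#'   to 0 with a warning).
#' @examples
#' screening_fraction(10.2, 19)   # ~0.46
#' @export
screening_fraction <- function(q_eff, n_backbone_charges = 19) {
  stopifnot(n_backbone_charges > 0)
  f <- 1 - q_eff / n_backbone_charges
  if (f < 0) {
    warning("effective charge exceeds bare charge; clamping fraction to 0")
    f <- 0
  }
  f
}

#' Manning counterion-condensation fraction
#'
#' For a line charge with spacing b, the Manning parameter is
#' xi = lB / b with lB the Bjerrum length; counterions condense when
#' xi > 1, neutralising a fraction 1 - 1/xi of the charge.  In water at
#' 300 K, lB ~ 0.71 nm.
#'
#' @param charge_spacing Axial charge spacing b in nm.
#' @param bjerrum_length Bjerrum length in nm (default 0.71).
#' @return Condensed fraction in \[0, 1).
#' @examples
#' manning_condensed_fraction(0.625, 0.71)   # ~0.12
#' @export
manning_condensed_fraction <- function(charge_spacing = 0.625,
                                       bjerrum_length = 0.71) {
  stopifnot(charge_spacing > 0, bjerrum_length > 0)
  xi <- bjerrum_length / charge_spacing
  max(0, 1 - 1 / xi)
}

#' Per-frame domain occupancy
#'
#' Assigns each bead to material B when the surface indicator at its
#' position exceeds 0.5, else to material A, and counts beads per frame:
#' a coarse-grained analogue of per-material contact numbers.
#'
#' @inheritParams end_to_end
#' @param pattern A non-uniform [surface_pattern()].
#' @return A tibble with columns `frame`, `time`, `n_A`, `n_B`
#'   (`n_A + n_B` equals the bead count).
#' @export
domain_occupancy <- function(traj, pattern) {
  stopifnot(inherits(pattern, "surface_pattern"))
  if (pattern$geometry == "uniform") {
    stop("domain occupancy is undefined for a uniform surface")
  }
  tr <- as_traj_tbl(traj)
  tr$in_B <- surface_indicator(tr$x, tr$y, pattern) > 0.5
  dplyr::summarise(
    dplyr::group_by(tr, .data$frame, .data$time),
    n_A = sum(!.data$in_B), n_B = sum(.data$in_B), .groups = "drop"
  )
}

#' Count points within a cutoff of another point set
#'
#' Number of points in `points_a` lying within `cutoff` of at least one
#' point of `points_b` (each a-point counted once): the coarse-grained
#' analogue of atom-contact counts at a 3.5 Å criterion.
#'
#' @param points_a,points_b Two-column matrices or data frames with
#'   `x`, `y` coordinates (nm).
#' @param cutoff Distance cutoff in nm (default 0.35).
#' @return Integer count.
#' @export
proximity_count <- function(points_a, points_b, cutoff = 0.35) {
  stopifnot(cutoff > 0)
  A <- as_positions(points_a)
  B <- as_positions(points_b)
  d2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
  sum(apply(d2 <= cutoff^2, 1, any))
}

#' Combined transport summary
#'
#' Bundles a mobility and a diffusion estimate into the derived
#' transport quantities: effective charge via the Einstein relation and
#' the screening fraction relative to the bare backbone charge, with the
#' Manning prediction alongside.
#'
#' @param mobility A `mobility_fit` or a mobility value (nm^2/(ns V)).
#' @param diffusion A `diffusion_fit` or a diffusion value (nm^2/ns).
#' @param temperature Kelvin.
#' @param n_backbone_charges Bare backbone charge count.
#' @param charge_spacing,bjerrum_length Passed to
#'   [manning_condensed_fraction()].
#' @return An object of class `transport_fit` with `mu`, `D`, `q_eff`,
#'   `screening`, `manning` fields.  Supports `tidy()` and `glance()`.
#' @export
transport_fit <- function(mobility, diffusion, temperature = 300,
                          n_backbone_charges = 19,
                          charge_spacing = 0.625, bjerrum_length = 0.71) {
  mu <- if (inherits(mobility, "mobility_fit")) mobility$mu else mobility
  D <- if (inherits(diffusion, "diffusion_fit")) diffusion$D else diffusion
  q <- effective_charge(mu, D, temperature)
  structure(
    list(
      mu = mu, D = D, q_eff = q,
      screening = screening_fraction(q, n_backbone_charges),
      manning = manning_condensed_fraction(charge_spacing, bjerrum_length),
      temperature = temperature,
      n_backbone_charges = n_backbone_charges
    ),
    class = "transport_fit"
  )
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat("<persistence_fit> lp =", format(x$lp, digits = 4), "+/-",
      format(x$lp_stderr, digits = 2), "nm  (a =",
      format(x$spacing, digits = 4), "nm; fit N =",
      x$fit_range[1], "..", x$fit_range[2], ")\n")
  invisible(x)
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("<diffusion_fit> D =", format(x$D, digits = 4), "+/-",
      format(x$D_stderr, digits = 2), "nm^2/ns (window",
      format(x$fit_window[1], digits = 3), "-",
      format(x$fit_window[2], digits = 3), "ns)\n")
  invisible(x)
}

#' @export
print.drift_fit <- function(x, ...) {
  cat("<drift_fit> v =", format(x$v, digits = 4), "+/-",
      format(x$v_stderr, digits = 2), "nm/ns\n")
  invisible(x)
}

#' @export
print.mobility_fit <- function(x, ...) {
  cat("<mobility_fit> mu =", format(x$mu, digits = 4), "nm^2/(ns V) from",
      nrow(x$data), "field point(s)\n")
  invisible(x)
}

#' @export
print.transport_fit <- function(x, ...) {
  cat("<transport_fit> mu =", format(x$mu, digits = 4), "nm^2/(ns V); D =",
      format(x$D, digits = 4), "nm^2/ns\n")
  cat("  q_eff =", format(x$q_eff, digits = 4), "e;  screened:",
      sprintf("%.1f%%", 100 * x$screening),
      sprintf("(Manning: %.1f%%)", 100 * x$manning), "\n")
  invisible(x)
}
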