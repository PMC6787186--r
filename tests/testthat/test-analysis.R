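# Trajectory estimators: geometry, worm-like-chain fits, MSD, transport
# arithmetic, occupancy and proximity.

test_that("end-to-end distance follows chain geometry", {
  p <- chain_params()
  lin <- init_chain(p, "linear")
  expect_equal(end_to_end(lin)$r_ee, 19 * 0.625)
  circ <- init_chain(p, "circular")
  R <- 20 * 0.625 / (2 * pi)
  expect_equal(end_to_end(circ)$r_ee, 2 * R * sin(19 * pi / 20),
               tolerance = 1e-12)
  p2 <- chain_params(n_beads = 2)
  expect_equal(end_to_end(init_chain(p2, "linear"))$r_ee, 0.625)
})

test_that("mean spacing averages bond lengths over frames", {
  p <- chain_params()
  expect_equal(mean_spacing(init_chain(p, "linear")), 0.625)
  # two frames with uniform spacings 0.6 and 0.65 average to 0.625
  f1 <- tibble::tibble(frame = 1, time = 0, bead = 1:3,
                       x = c(0, 0.6, 1.2), y = 0)
  f2 <- tibble::tibble(frame = 2, time = 1, bead = 1:3,
                       x = c(0, 0.65, 1.3), y = 0)
  expect_equal(mean_spacing(rbind(f1, f2)), 0.625)
})

test_that("tangent correlations are exact on constructed conformations", {
  p <- chain_params()
  corr <- tangent_correlation(init_chain(p, "linear"))
  expect_true(all(abs(corr$correlation - 1) < 1e-12))
  # alternating +/-90 degree zigzag: C(1) = 0
  zig <- chain_from_angles(rep(c(pi / 2, -pi / 2), length.out = 18))
  cz <- tangent_correlation(zig, max_sep = 2)
  expect_equal(cz$correlation[1], 0, tolerance = 1e-12)
  expect_true(all(cz$correlation >= -1 & cz$correlation <= 1))
})

test_that("C(1) of ideal worm-like-chain angle samples matches the Bessel-ratio quadrature", {
  set.seed(77)
  kappa <- 1.7
  frames <- lapply(1:400, function(f) {
    st <- chain_from_angles(sample_wlc_angles(18, kappa))
    st$frame <- f; st$time <- f - 1
    st
  })
  traj <- dplyr::bind_rows(frames)
  c1 <- tangent_correlation(traj, max_sep = 1)
  target <- quad_mean_cos(kappa)
  n_ang <- 400 * 18
  se <- sqrt(stats::var(cos(sample_wlc_angles(5000, kappa))) / n_ang)
  expect_lt(abs(c1$correlation - target), 3 * se + 1e-4)
})

test_that("persistence-length fit inverts an exact exponential decay", {
  for (pars in list(c(lp = 1.39, a = 0.625), c(lp = 1, a = 1),
                    c(lp = 4.2, a = 0.3))) {
    corr <- tibble::tibble(separation = 1:6,
                           correlation = exp(-(1:6) * pars["a"] / pars["lp"]))
    fit <- fit_persistence_length(corr, spacing = pars[["a"]])
    expect_equal(fit$lp, pars[["lp"]], tolerance = 1e-10)
  }
})

test_that("persistence-length fit guards against unusable correlations", {
  corr <- tibble::tibble(separation = 1:6,
                         correlation = c(0.6, 0.4, 0.2, -0.05, 0.1, 0.05))
  expect_warning(fit <- fit_persistence_length(corr, spacing = 0.625),
                 "non-positive")
  expect_gt(fit$lp, 0)
  bad <- tibble::tibble(separation = 1:3, correlation = c(0.5, -1, -1))
  expect_error(suppressWarnings(fit_persistence_length(bad, spacing = 1)),
               "fewer than 2")
})

test_that("centre-of-mass series reflects rigid translation", {
  p <- chain_params(n_beads = 4)
  st <- init_chain(p, "linear")
  frames <- lapply(0:5, function(k) {
    s <- st; s$x <- s$x + 0.3 * k; s$frame <- k + 1; s$time <- k * 0.1
    s
  })
  cs <- com_series(dplyr::bind_rows(frames), "x")
  expect_equal(unname(coef(lm(com ~ time, data = cs))[2]), 3,
               tolerance = 1e-10)
  cs_y <- com_series(dplyr::bind_rows(frames), "y")
  expect_true(all(abs(diff(cs_y$com)) < 1e-12))
})

test_that("MSD obeys its closed forms and basic properties", {
  # constant series -> zero at all lags
  s0 <- tibble::tibble(time = 0:20, com = 5)
  expect_true(all(msd(s0)$msd == 0))
  # linear ramp X = v t -> v^2 dt^2
  v <- 3
  s1 <- tibble::tibble(time = (0:40) * 0.5, com = v * (0:40) * 0.5)
  m1 <- msd(s1, max_lag = 10)
  expect_equal(m1$msd, v^2 * m1$lag^2, tolerance = 1e-10)
  expect_true(all(m1$msd >= 0))
  # Gaussian random walk: slope/2 recovers D within 3 standard errors;
  # the relative sampling SD of a time-averaged MSD at lag tau is about
  # sqrt(4 tau / (3 T)) for Brownian motion
  D <- 0.25; dt <- 0.1
  n <- 4000; tau_max <- 40 * dt
  ser <- toy_series(n, D, dt, seed = 5)
  fit <- fit_diffusion(msd(ser, max_lag = tau_max), fit_window = c(dt, tau_max))
  se_bound <- sqrt(4 * tau_max / (3 * n * dt)) * D
  expect_lt(abs(fit$D - D), 3 * se_bound)
})

test_that("diffusion fit inverts exact MSD lines and rejects negative slopes", {
  curve <- tibble::tibble(lag = (1:10) * 0.5, msd = 2 * 0.13 * (1:10) * 0.5)
  expect_equal(fit_diffusion(curve, c(0, 10))$D, 0.13, tolerance = 1e-12)
  curve2 <- tibble::tibble(lag = 1:10, msd = 2 * (1:10))
  expect_equal(fit_diffusion(curve2, c(1, 10))$D, 1, tolerance = 1e-12)
  dec <- tibble::tibble(lag = 1:10, msd = seq(10, 1))
  expect_error(fit_diffusion(dec, c(1, 10)), "negative MSD slope")
})

test_that("drift velocity is the least-squares slope of X(t)", {
  s <- tibble::tibble(time = 0:50, com = 3 * (0:50))
  expect_equal(drift_velocity(s)$v, 3, tolerance = 1e-12)
  expect_equal(drift_velocity(tibble::tibble(time = 0:50, com = 7))$v, 0,
               tolerance = 1e-12)
  set.seed(3)
  sn <- tibble::tibble(time = (0:200) * 0.1,
                       com = 3 * (0:200) * 0.1 + rnorm(201, 0, 0.4))
  d <- drift_velocity(sn)
  expect_lt(abs(d$v - 3), 3 * d$v_stderr)
})

test_that("mobility fit is the through-origin slope of v against E", {
  expect_equal(fit_mobility(tibble::tibble(E = 0.01, v = 0.516))$mu, 51.6)
  pts <- tibble::tibble(E = c(0.002, 0.005, 0.01), v = 51.6 * E)
  expect_equal(fit_mobility(pts)$mu, 51.6, tolerance = 1e-12)
  expect_error(fit_mobility(tibble::tibble(E = 0, v = 0)), "nonzero-field")
})

test_that("Einstein-relation charge, screening and Manning arithmetic", {
  expect_equal(effective_charge(51.6, 0.13, 300), 10.26, tolerance = 1e-3)
  expect_equal(effective_charge(0, 0.13, 300), 0)
  mu_unit <- 0.13 / thermal_voltage(300)
  expect_equal(effective_charge(mu_unit, 0.13, 300), 1, tolerance = 1e-12)

  expect_equal(screening_fraction(10.2, 19), 0.463, tolerance = 1e-3)
  expect_equal(screening_fraction(19, 19), 0)
  expect_equal(screening_fraction(0, 19), 1)
  expect_warning(f <- screening_fraction(25, 19), "clamping")
  expect_equal(f, 0)
  # complementarity: screening + q/n = 1 exactly
  q <- 7.3
  expect_equal(screening_fraction(q, 19) + q / 19, 1, tolerance = 1e-15)

  expect_equal(manning_condensed_fraction(0.625, 0.71), 0.1197,
               tolerance = 1e-3)
  expect_equal(manning_condensed_fraction(0.8, 0.71), 0)   # below threshold
  expect_equal(manning_condensed_fraction(0.355, 0.71), 0.5)
})

test_that("domain occupancy assigns beads by the indicator and sums to n", {
  p <- chain_params()
  pat <- surface_pattern("stripe")
  on_stripe <- init_chain(p, "linear")               # along y = 0
  occ <- domain_occupancy(on_stripe, pat)
  expect_equal(occ$n_B, 20)
  expect_equal(occ$n_A, 0)
  off <- on_stripe; off$y <- off$y + 0.9 + 10 * pat$smoothing
  occ2 <- domain_occupancy(off, pat)
  expect_equal(occ2$n_A, 20)
  expect_true(all(occ$n_A + occ$n_B == 20))
  expect_error(domain_occupancy(on_stripe, surface_pattern("uniform")),
               "uniform")
})

test_that("proximity count matches the brute-force all-pairs oracle", {
  expect_equal(proximity_count(cbind(0, 0), cbind(0.34, 0), 0.35), 1)
  expect_equal(proximity_count(cbind(0, 0), cbind(0.36, 0), 0.35), 0)
  set.seed(11)
  for (k in 1:5) {
    A <- matrix(runif(100, 0, 3), ncol = 2)
    B <- matrix(runif(100, 0, 3), ncol = 2)
    expect_identical(proximity_count(A, B, 0.35),
                     brute_proximity(A, B, 0.35))
  }
})

test_that("tidiers expose fit results as tibbles", {
  corr <- tibble::tibble(separation = 1:6,
                         correlation = exp(-(1:6) * 0.625 / 1.39))
  fit <- fit_persistence_length(corr, spacing = 0.625)
  td <- tidy(fit)
  expect_identical(td$term, c("lp", "slope"))
  expect_equal(td$estimate[1], 1.39, tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(gl$r.squared, 1, tolerance = 1e-10)

  tf <- transport_fit(51.6, 0.13)
  tt <- tidy(tf)
  expect_identical(tt$term, c("mu", "D", "q_eff", "screening", "manning"))
  expect_equal(glance(tf)$q_eff, 10.26, tolerance = 1e-3)
})
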