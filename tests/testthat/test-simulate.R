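# Brownian-dynamics integrator and scenario presets.

test_that("initial conformations have the stated geometry", {
  p <- chain_params()
  lin <- init_chain(p, "linear")
  expect_equal(diff(lin$x), rep(0.625, 19))
  expect_equal(lin$y, rep(0, 20))
  circ <- init_chain(p, "circular")
  R <- 20 * 0.625 / (2 * pi)
  expect_equal(R, 1.989, tolerance = 1e-3)
  expect_equal(sqrt(circ$x^2 + circ$y^2), rep(R, 20), tolerance = 1e-12)
  rw1 <- init_chain(p, "random_walk", rng_seed = 5)
  rw2 <- init_chain(p, "random_walk", rng_seed = 5)
  expect_identical(rw1, rw2)
  # all conformations keep the rest bond length
  expect_equal(mean_spacing(rw1), 0.625, tolerance = 1e-12)
  # placement offset moves the centre of mass
  off <- init_chain(p, "linear", offset = c(-2, 1))
  expect_equal(c(mean(off$x), mean(off$y)), c(-2, 1), tolerance = 1e-12)
})

test_that("time step guard enforces the bond-relaxation stability criterion", {
  p <- chain_params()
  expect_equal(bd_max_dt(p), 0.1 * p$bead_friction / p$bond_stiffness)
  expect_error(
    bd_simulate(p, init_chain(p, "linear"), n_steps = 10,
                dt = 2 * bd_max_dt(p)),
    "stability"
  )
})

test_that("free centre-of-mass displacements are unbiased with variance 2 kBT dt / (n gamma)", {
  p <- chain_params(n_beads = 2)
  tr <- bd_simulate(p, init_chain(p, "linear"), n_steps = 2e4,
                    sample_every = 1, seed = 21)
  cs <- com_series(tr, "x")
  dx <- diff(cs$com)
  dt <- diff(cs$time)[1]
  # COM of an isolated chain feels no net force: increments are pure noise
  sigma2 <- 2 * dt / (2 * p$bead_friction)   # two beads
  expect_lt(abs(mean(dx)), 3 * sqrt(sigma2 / length(dx)))
  expect_equal(var(dx), sigma2, tolerance = 0.05)
})

test_that("bond-length fluctuations satisfy equipartition against the quadrature oracle", {
  p <- chain_params(n_beads = 2)
  tr <- bd_simulate(p, init_chain(p, "linear"), n_steps = 1e6,
                    sample_every = 20, seed = 8)
  m <- cbind(tr$x[tr$bead == 2] - tr$x[tr$bead == 1],
             tr$y[tr$bead == 2] - tr$y[tr$bead == 1])
  blen <- sqrt(rowSums(m^2))
  # oracle: radial density p(r) ~ r exp(-k (r-a)^2 / 2) in 2D
  k <- p$bond_stiffness; a <- p$bond_length
  Z <- integrate(function(r) r * exp(-k * (r - a)^2 / 2), 0, Inf)$value
  m1 <- integrate(function(r) r^2 * exp(-k * (r - a)^2 / 2), 0, Inf)$value / Z
  m2 <- integrate(function(r) r^3 * exp(-k * (r - a)^2 / 2), 0, Inf)$value / Z
  expect_equal(mean(blen), m1, tolerance = 0.01)
  expect_equal(var(blen), m2 - m1^2, tolerance = 0.05)
})

test_that("identical scenario and seed give bit-identical trajectories", {
  sc <- scenario("stripe_confinement", n_steps = 5000, sample_every = 100,
                 seed = 99)
  t1 <- run_scenario(sc)
  t2 <- run_scenario(sc)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  t3 <- run_scenario(scenario("stripe_confinement", n_steps = 5000,
                              sample_every = 100, seed = 100))
  expect_false(identical(t1$x, t3$x))
})

test_that("zero-field driven transport shows no systematic drift", {
  v <- sapply(1:4, function(s) {
    tr <- run_scenario(scenario("driven_transport", field_E = 0,
                                n_steps = 2e5, discard_frac = 0, seed = s))
    cs <- com_series(tr, "x")
    drift_velocity(cs)$v
  })
  # exact sampling SD of the OLS slope for Brownian COM motion:
  # Var(beta) = c' K c / (c'c)^2 with K_ij = 2 D min(t_i, t_j)
  tr <- run_scenario(scenario("driven_transport", field_E = 0,
                              n_steps = 2e5, discard_frac = 0, seed = 1))
  tt <- unique(tr$time)
  cc <- tt - mean(tt)
  D <- 0.13
  K <- 2 * D * outer(tt, tt, pmin)
  se_v <- sqrt(drop(cc %*% K %*% cc)) / sum(cc^2)
  z <- mean(v) / (se_v / sqrt(length(v)))
  expect_lt(abs(z), 4)
})

test_that("free-chain centre-of-mass diffusion obeys the Einstein relation", {
  p <- chain_params()
  D_hat <- sapply(1:3, function(s) {
    tr <- run_scenario(scenario("free_uniform", params = p, n_steps = 1e6,
                                sample_every = 100, discard_frac = 0,
                                seed = 400 + s))
    fit_diffusion(msd(com_series(tr, "x"), max_lag = 1.0))$D
  })
  D_expect <- 1 / (p$n_beads * p$bead_friction)   # kBT/(n gamma) = 0.13
  expect_equal(D_expect, 0.13, tolerance = 1e-12)
  expect_equal(mean(D_hat), D_expect, tolerance = 0.15)
})

test_that("trajectories carry full provenance and equilibration is discarded", {
  sc <- scenario("free_uniform", n_steps = 1e4, sample_every = 100,
                 discard_frac = 0.1, seed = 2)
  tr <- run_scenario(sc)
  prov <- trajectory_provenance(tr)
  expect_equal(prov$seed, 2)
  expect_identical(prov$scenario, "free_uniform")
  expect_equal(prov$dt, 1.5e-4)
  expect_true(min(tr$time) >= 0.1 * 1e4 * prov$dt)
  tt <- unique(tr$time)
  expect_equal(diff(tt), rep(diff(tt)[1], length(tt) - 1), tolerance = 1e-12)
})

test_that("stripe confinement stretches the chain to near the closed-form extensions", {
  # the soft tanh walls confine slightly differently from the hard-wall
  # channel of the closed forms; the model tracks both predictions to
  # within 15% (the two predictions themselves differ by ~3%)
  ext <- mean(vapply(41:42, function(s) {
    tr <- run_scenario(scenario("stripe_confinement", n_steps = 1e7,
                                discard_frac = 1 / 3, seed = s))
    mean(end_to_end(tr)$r_ee)
  }, numeric(1)))
  th <- confinement_theory()
  expect_equal(ext, th$degennes_extension, tolerance = 0.15)
  expect_equal(ext, th$odijk_extension, tolerance = 0.15)
  # and far above the free-chain end-to-end distance (~ sqrt(2 lp lc))
  expect_gt(ext, sqrt(2 * 1.39 * 12.5))
})

test_that("a chain released near the boundary ends up on the strong-binding side", {
  final_B <- sapply(1:10, function(s) {
    tr <- run_scenario(scenario("boundary_crossing", n_steps = 1e6,
                                seed = 500 + s))
    occ <- domain_occupancy(tr, trajectory_provenance(tr)$pattern)
    occ$n_B[nrow(occ)]
  })
  expect_gte(sum(final_B == 20), 9)
})
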