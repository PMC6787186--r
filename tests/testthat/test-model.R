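# Chain/surface/field energy model and its analytic forces.

test_that("surface indicator matches the tanh closed forms", {
  pat <- surface_pattern("stripe", stripe_width = 1.8, smoothing = 0.3)
  # stripe centre: 0.5*(tanh(3) - tanh(-3))
  expect_equal(surface_indicator(0, 0, pat), tanh(3), tolerance = 1e-12)
  expect_equal(surface_indicator(5, 0, pat), tanh(3), tolerance = 1e-12)
  # stripe edges: ~1/2 by symmetry of the tanh profile (w >> delta)
  expect_equal(surface_indicator(0, 0.9, pat), 0.5, tolerance = 2e-3)
  expect_equal(surface_indicator(0, -0.9, pat), 0.5, tolerance = 2e-3)
  # far outside
  expect_lt(surface_indicator(0, 10, pat), 1e-8)

  bnd <- surface_pattern("single_boundary")
  expect_lt(surface_indicator(-10 * bnd$smoothing, 3, bnd), 1e-8)
  expect_gt(surface_indicator(10 * bnd$smoothing, -3, bnd), 1 - 1e-8)
  expect_equal(surface_indicator(0, 0, bnd), 0.5)

  uni <- surface_pattern("uniform")
  expect_identical(surface_indicator(c(-3, 0, 3), c(1, 2, 3), uni),
                   c(0, 0, 0))
})

test_that("surface indicator is monotone across a boundary and even in y for a stripe", {
  bnd <- surface_pattern("single_boundary")
  xs <- seq(-3, 3, length.out = 101)
  expect_true(all(diff(surface_indicator(xs, 0, bnd)) > 0))
  pat <- surface_pattern("stripe")
  ys <- seq(-4, 4, length.out = 81)
  s <- surface_indicator(rep(0, 81), ys, pat)
  expect_equal(s, rev(s), tolerance = 1e-12)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("energy terms vanish at the rest configuration and follow closed forms", {
  p <- chain_params()
  st <- init_chain(p, "linear")
  e <- chain_energy(st, p)
  expect_equal(e$bond, 0, tolerance = 1e-20)
  expect_equal(e$bend, 0, tolerance = 1e-12)
  expect_equal(e$excluded_volume, 0)
  expect_equal(e$surface, 0)
  expect_equal(e$field, 0)

  # bond harmonicity on a dimer: U = 1/2 k a^2 eps^2 at separation a(1+eps)
  p2 <- chain_params(n_beads = 2)
  for (eps in c(-0.05, 0.08)) {
    st2 <- tibble::tibble(x = c(0, p2$bond_length * (1 + eps)), y = c(0, 0))
    expect_equal(chain_energy(st2, p2)$total,
                 0.5 * p2$bond_stiffness * p2$bond_length^2 * eps^2,
                 tolerance = 1e-12)
  }

  # 20 beads on the stripe centre line: surface term = 20 * delta_eps * s(0)
  pat <- surface_pattern("stripe")
  e3 <- chain_energy(init_chain(p, "linear"), p, pat)
  expect_equal(e3$surface, 20 * kcal_to_kbt(-6.1) * tanh(3), tolerance = 1e-9)
  expect_equal(e3$surface, -203.6, tolerance = 1e-3)
})

test_that("bead-count mismatch is a contract violation", {
  p <- chain_params(n_beads = 10)
  expect_error(chain_energy(init_chain(chain_params(n_beads = 5), "linear"), p),
               "5 beads")
  expect_error(chain_forces(init_chain(chain_params(n_beads = 5), "linear"), p),
               "expect")
})

test_that("soft excluded volume penalises only non-bonded overlaps", {
  p <- chain_params(n_beads = 4, excluded_volume = TRUE)
  # fold the chain: bead 4 sits half a diameter from beads 1 and 2
  st <- tibble::tibble(x = c(0, 0.625, 0.625, 0.3125), y = c(0, 0, 0.625, 0))
  e <- chain_energy(st, p)
  expect_equal(e$excluded_volume, 2 * (1 - 0.3125 / 0.625)^2, tolerance = 1e-9)
  # beyond the diameter the term vanishes
  st2 <- st; st2$x[4] <- -1
  expect_equal(chain_energy(st2, p)$excluded_volume, 0)
  # the identical configuration without the flag carries no EV energy
  p0 <- chain_params(n_beads = 4, excluded_volume = FALSE)
  expect_equal(chain_energy(st, p0)$excluded_volume, 0)
})

test_that("forces equal the negative energy gradient on random configurations", {
  set.seed(1234)
  p <- chain_params(n_beads = 8, excluded_volume = TRUE)
  pat <- surface_pattern("stripe")
  fl <- field_spec(E = 0.004)
  worst <- 0
  for (k in 1:100) {
    st <- init_chain(p, "random_walk")
    st$x <- st$x + rnorm(8, 0, 0.08)
    st$y <- st$y + rnorm(8, 0, 0.08)
    fa <- chain_forces(st, p, pat, fl)
    fn <- fd_forces(st, p, pat, fl)
    scale <- pmax(1e-3, abs(fn))
    worst <- max(worst, max(abs(cbind(fa$fx, fa$fy) - fn) / scale))
  }
  expect_lt(worst, 1e-5)
})

test_that("forces are translation invariant where the landscape is", {
  set.seed(9)
  p <- chain_params(n_beads = 6)
  st <- init_chain(p, "random_walk")
  pat <- surface_pattern("stripe")
  # stripe landscape is x-invariant: energies unchanged by any x shift
  st2 <- st; st2$x <- st2$x + 17.3
  e1 <- chain_energy(st, p, pat)
  e2 <- chain_energy(st2, p, pat)
  expect_equal(e1$total, e2$total, tolerance = 1e-10)
  # uniform surface, no field: invariant under arbitrary rigid translation
  st3 <- st; st3$x <- st3$x + 4.2; st3$y <- st3$y - 7.7
  expect_equal(chain_energy(st, p)$total, chain_energy(st3, p)$total,
               tolerance = 1e-10)
})

test_that("field force on a charged bead is q E / (kBT/e)", {
  p <- chain_params(n_beads = 2, bead_charge = 0.51)
  fl <- field_spec(E = 0.01)
  f <- chain_forces(init_chain(p, "linear"), p, field = fl)
  expect_equal(f$fx, rep(0.51 * 0.01 / thermal_voltage(300), 2),
               tolerance = 1e-12)
  expect_equal(f$fy, c(0, 0))
})

test_that("field spec enforces E = V/Lx consistency", {
  expect_equal(field_spec(voltage = 0.2, box_length = 40)$E, 0.005)
  expect_error(field_spec(E = 0.01, voltage = 0.2, box_length = 40),
               "inconsistent")
  expect_error(field_spec(voltage = 0.2), "box_length")
})
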