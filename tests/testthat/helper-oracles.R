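# Independent oracles used across the suite.

# Central finite-difference gradient of the total potential energy.
fd_forces <- function(state, params, pattern, field, h = 1e-6) {
  st <- as.data.frame(state)
  n <- nrow(st)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    for (j in 1:2) {
      cc <- c("x", "y")[j]
      sp <- st; sm <- st
      sp[[cc]][i] <- sp[[cc]][i] + h
      sm[[cc]][i] <- sm[[cc]][i] - h
      ep <- chain_energy(sp, params, pattern, field)$total
      em <- chain_energy(sm, params, pattern, field)$total
      out[i, j] <- -(ep - em) / (2 * h)
    }
  }
  out
}

# Rejection sampler for joint angles of the ideal 2D discrete chain with
# bending energy kappa*(1 - cos(theta)): p(theta) ~ exp(kappa * cos theta)
# on (-pi, pi).  Independent of the simulator.
sample_wlc_angles <- function(n, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    th <- stats::runif(2 * n, -pi, pi)
    acc <- stats::runif(2 * n) < exp(kappa * (cos(th) - 1))
    out <- c(out, th[acc])
  }
  out[seq_len(n)]
}

# Build a single-frame chain state from a sequence of joint angles.
chain_from_angles <- function(angles, a = 0.625) {
  phi <- cumsum(c(0, angles))       # bond headings
  x <- cumsum(c(0, a * cos(phi)))
  y <- cumsum(c(0, a * sin(phi)))
  tibble::tibble(bead = seq_along(x), x = x, y = y)
}

# Mean cos(theta) of the ideal 2D chain by numerical quadrature:
# the Bessel ratio I1(kappa)/I0(kappa).
quad_mean_cos <- function(kappa) {
  num <- stats::integrate(function(t) cos(t) * exp(kappa * cos(t)),
                          -pi, pi, rel.tol = 1e-10)$value
  den <- stats::integrate(function(t) exp(kappa * cos(t)),
                          -pi, pi, rel.tol = 1e-10)$value
  num / den
}

# Quadratic-time proximity count oracle.
brute_proximity <- function(A, B, cutoff) {
  cnt <- 0L
  for (i in seq_len(nrow(A))) {
    hit <- FALSE
    for (j in seq_len(nrow(B))) {
      if (sqrt(sum((A[i, ] - B[j, ])^2)) <= cutoff) { hit <- TRUE; break }
    }
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

# Small random-walk trajectory tibble for estimator tests.
toy_series <- function(n, D, dt, seed) {
  set.seed(seed)
  tibble::tibble(time = (0:(n - 1)) * dt,
                 com = cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(2 * D * dt)))))
}
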