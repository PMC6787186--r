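#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coarse-grained force field for a 2D bead-spring worm-like chain on a
// patterned adhesive surface.  Units: nm, ns, kBT, e.  The same routine
// backs the exported force evaluator and the Brownian-dynamics loop.

struct ModelSpec {
  double a, k_bond, kappa;
  int ev_on;
  double ev_d, ev_eps;
  int geom;                 // 0 uniform, 1 single boundary, 2 stripe
  double delta_eps, w, smooth;
  double f_field;           // per-bead field force along +x, kBT/nm
  double gamma;             // per-bead friction, kBT ns/nm^2
};

static ModelSpec parse_spec(const List& spec) {
  ModelSpec m;
  m.a = spec["a"]; m.k_bond = spec["k_bond"]; m.kappa = spec["kappa"];
  m.ev_on = spec["ev_on"]; m.ev_d = spec["ev_d"]; m.ev_eps = spec["ev_eps"];
  m.geom = spec["geom"]; m.delta_eps = spec["delta_eps"];
  m.w = spec["w"]; m.smooth = spec["smooth"];
  m.f_field = spec["f_field"]; m.gamma = spec["gamma"];
  return m;
}

static inline double sech2(double z) {
  double c = std::cosh(z);
  return 1.0 / (c * c);
}

// Fills fx, fy with forces; returns the largest bond length (for the
// integrator's stability check).
static double compute_forces(const double* x, const double* y, int n,
                             const ModelSpec& m, double* fx, double* fy) {
  for (int i = 0; i < n; ++i) { fx[i] = m.f_field; fy[i] = 0.0; }

  // bonds
  double max_bond = 0.0;
  std::vector<double> ux(n - 1), uy(n - 1), bl(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r <= 0.0) stop("degenerate (zero-length) bond at bead %d", i + 1);
    bl[i] = r; ux[i] = dx / r; uy[i] = dy / r;
    if (r > max_bond) max_bond = r;
    double fmag = m.k_bond * (r - m.a);   // pull together when stretched
    fx[i]     += fmag * ux[i]; fy[i]     += fmag * uy[i];
    fx[i + 1] -= fmag * ux[i]; fy[i + 1] -= fmag * uy[i];
  }

  // bending: U = kappa * (1 - cos theta) per interior joint
  for (int j = 0; j < n - 2; ++j) {
    double c = ux[j] * ux[j + 1] + uy[j] * uy[j + 1];
    // F = -grad U = +kappa * grad(cos theta); with u = r_{j+1}-r_j,
    // v = r_{j+2}-r_{j+1}: d(cos)/dr_j = -(v/(|u||v|) - c*u/|u|^2), etc.
    double inv_uv = 1.0 / (bl[j] * bl[j + 1]);
    double vx = ux[j + 1] * bl[j + 1], vy = uy[j + 1] * bl[j + 1];
    double wx = ux[j] * bl[j], wy = uy[j] * bl[j];
    double inv_u2 = 1.0 / (bl[j] * bl[j]);
    double inv_v2 = 1.0 / (bl[j + 1] * bl[j + 1]);
    double dA_x = -(vx * inv_uv - c * wx * inv_u2);
    double dA_y = -(vy * inv_uv - c * wy * inv_u2);
    double dC_x = wx * inv_uv - c * vx * inv_v2;
    double dC_y = wy * inv_uv - c * vy * inv_v2;
    double dB_x = -(dA_x + dC_x);
    double dB_y = -(dA_y + dC_y);
    fx[j]     += m.kappa * dA_x; fy[j]     += m.kappa * dA_y;
    fx[j + 1] += m.kappa * dB_x; fy[j + 1] += m.kappa * dB_y;
    fx[j + 2] += m.kappa * dC_x; fy[j + 2] += m.kappa * dC_y;
  }

  // soft excluded volume between non-bonded pairs: U = eps*(1 - r/d)^2, r < d
  if (m.ev_on) {
    double d2 = m.ev_d * m.ev_d;
    for (int i = 0; i < n - 2; ++i) {
      for (int j = i + 2; j < n; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double r2 = dx * dx + dy * dy;
        if (r2 < d2) {
          double r = std::sqrt(r2);
          if (r <= 0.0) continue;            // exactly coincident: no direction
          double fmag = 2.0 * m.ev_eps * (1.0 - r / m.ev_d) / m.ev_d; // repulsive
          double fxp = fmag * dx / r, fyp = fmag * dy / r;
          fx[j] += fxp; fy[j] += fyp;
          fx[i] -= fxp; fy[i] -= fyp;
        }
      }
    }
  }

  // surface adhesion: U = delta_eps * s(r); F = -delta_eps * grad s
  if (m.geom == 1) {
    double inv2d = 0.5 / m.smooth;
    for (int i = 0; i < n; ++i)
      fx[i] -= m.delta_eps * inv2d * sech2(x[i] / m.smooth);
  } else if (m.geom == 2) {
    double w2 = 0.5 * m.w, inv2d = 0.5 / m.smooth;
    for (int i = 0; i < n; ++i) {
      double ds = inv2d * (sech2((y[i] + w2) / m.smooth) -
                           sech2((y[i] - w2) / m.smooth));
      fy[i] -= m.delta_eps * ds;
    }
  }

  return max_bond;
}

// [[Rcpp::export]]
NumericMatrix forces_cpp(NumericMatrix pos, List spec) {
  ModelSpec m = parse_spec(spec);
  int n = pos.nrow();
  std::vector<double> x(n), y(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  compute_forces(x.data(), y.data(), n, m, fx.data(), fy.data());
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// Euler-Maruyama overdamped Langevin integration.  Uses R's RNG so that
// set.seed() in R makes runs bit-reproducible.  Samples the state every
// `sample_every` steps (including step 0); coordinates are never wrapped.
// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix pos0, List spec, double dt,
                int n_steps, int sample_every) {
  ModelSpec m = parse_spec(spec);
  int n = pos0.nrow();
  if (n_steps < 1 || sample_every < 1) stop("n_steps and sample_every must be >= 1");

  std::vector<double> x(n), y(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); }

  int n_frames = n_steps / sample_every + 1;
  NumericVector frames(Dimension(n, 2, n_frames));
  NumericVector times(n_frames);

  double mob = dt / m.gamma;                    // mobility * dt
  double noise = std::sqrt(2.0 * dt / m.gamma); // kBT = 1
  double bond_limit = 3.0 * m.a;

  int f = 0;
  for (int i = 0; i < n; ++i) { frames[i] = x[i]; frames[n + i] = y[i]; }
  times[0] = 0.0; f = 1;

  for (int step = 1; step <= n_steps; ++step) {
    double max_bond = compute_forces(x.data(), y.data(), n, m,
                                     fx.data(), fy.data());
    if (max_bond > bond_limit)
      stop("integration unstable at step %d: bond length %.3f nm exceeds 3a",
           step, max_bond);
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]))
        stop("non-finite force on bead %d at step %d", i + 1, step);
      x[i] += fx[i] * mob + noise * norm_rand();
      y[i] += fy[i] * mob + noise * norm_rand();
    }
    if (step % sample_every == 0) {
      std::size_t off = (std::size_t)f * 2 * n;
      for (int i = 0; i < n; ++i) {
        frames[off + i] = x[i];
        frames[off + n + i] = y[i];
      }
      times[f] = step * dt;
      ++f;
    }
  }

  return List::create(_["frames"] = frames, _["times"] = times);
}
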