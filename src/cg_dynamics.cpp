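#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped (position-Langevin) Brownian dynamics:
//   dx = (F / gamma) dt + sqrt(2 kT dt / gamma) * xi
// Forces: harmonic springs (backbone, bend, inter-chain cross-links),
// attractive Gaussian contact wells U(r) = -eps * exp(-(r-r0)^2 / (2 w^2))
// between tip beads of opposing dimers (minimum at the contact distance
// r0, so the well both binds and keeps the chains from collapsing), and a
// constant per-bead steering force. Draws use R's RNG so results are
// reproducible under set.seed().
//
// [[Rcpp::export(name = ".cg_run")]]
List cg_run(NumericMatrix coords,
            IntegerVector spring_i, IntegerVector spring_j,
            NumericVector spring_k, NumericVector spring_r0,
            IntegerVector pair_i, IntegerVector pair_j,
            double eps, double well_width, double well_r0,
            NumericMatrix steer,        // n x 3 per-bead force (kT/A)
            double gamma, double kT, double dt,
            int n_steps, int stride, double max_disp) {
  const int n = coords.nrow();
  const int ns = spring_i.size();
  const int np = pair_i.size();
  std::vector<double> x(n), y(n), z(n);
  for (int a = 0; a < n; ++a) {
    x[a] = coords(a, 0); y[a] = coords(a, 1); z[a] = coords(a, 2);
  }
  std::vector<double> fx(n), fy(n), fz(n);
  const double noise = (kT > 0.0) ? std::sqrt(2.0 * kT * dt / gamma) : 0.0;
  const double inv_gamma_dt = dt / gamma;
  const double w2 = well_width * well_width;
  const double cut2 = 12.25 * w2;  // (3.5 w)^2 truncation of the well
  const int n_frames = n_steps / stride + 1;
  NumericVector frames(Dimension(n, 3, n_frames));
  NumericVector times(n_frames);
  int fidx = 0;
  for (int a = 0; a < n; ++a) {
    frames[a] = x[a]; frames[n + a] = y[a]; frames[2 * n + a] = z[a];
  }
  times[0] = 0.0;
  RNGScope rng;
  const double max_disp2 = max_disp * max_disp;

  for (int step = 1; step <= n_steps; ++step) {
    for (int a = 0; a < n; ++a) {
      fx[a] = steer(a, 0); fy[a] = steer(a, 1); fz[a] = steer(a, 2);
    }
    for (int s = 0; s < ns; ++s) {
      const int i = spring_i[s], j = spring_j[s];
      const double dxx = x[j] - x[i], dyy = y[j] - y[i], dzz = z[j] - z[i];
      const double r = std::sqrt(dxx * dxx + dyy * dyy + dzz * dzz);
      if (r < 1e-12) continue;
      const double f = spring_k[s] * (r - spring_r0[s]) / r;
      fx[i] += f * dxx; fy[i] += f * dyy; fz[i] += f * dzz;
      fx[j] -= f * dxx; fy[j] -= f * dyy; fz[j] -= f * dzz;
    }
    if (eps > 0.0) {
      for (int p = 0; p < np; ++p) {
        const int i = pair_i[p], j = pair_j[p];
        const double dxx = x[j] - x[i], dyy = y[j] - y[i], dzz = z[j] - z[i];
        const double r2 = dxx * dxx + dyy * dyy + dzz * dzz;
        const double r = std::sqrt(r2);
        const double dr = r - well_r0;
        if (dr * dr > cut2 || r < 1e-12) continue;
        // F_i = (dU/dr) * rhat toward j for r > r0, away for r < r0
        const double f = (eps * dr / w2) * std::exp(-0.5 * dr * dr / w2) / r;
        fx[i] += f * dxx; fy[i] += f * dyy; fz[i] += f * dzz;
        fx[j] -= f * dxx; fy[j] -= f * dyy; fz[j] -= f * dzz;
      }
    }
    for (int a = 0; a < n; ++a) {
      double ddx = fx[a] * inv_gamma_dt;
      double ddy = fy[a] * inv_gamma_dt;
      double ddz = fz[a] * inv_gamma_dt;
      if (noise > 0.0) {
        ddx += noise * norm_rand();
        ddy += noise * norm_rand();
        ddz += noise * norm_rand();
      }
      if (ddx * ddx + ddy * ddy + ddz * ddz > max_disp2) {
        stop("integration unstable: per-step displacement exceeded the bond "
             "length at step %d; use a smaller timestep", step);
      }
      x[a] += ddx; y[a] += ddy; z[a] += ddz;
    }
    if (step % stride == 0) {
      ++fidx;
      const R_xlen_t base = (R_xlen_t)fidx * 3 * n;
      for (int a = 0; a < n; ++a) {
        frames[base + a] = x[a];
        frames[base + n + a] = y[a];
        frames[base + 2 * n + a] = z[a];
      }
      times[fidx] = step * dt;
    }
  }
  return List::create(_["frames"] = frames, _["times"] = times);
}
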