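#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Box-constrained least squares for y ~ a * x + c given precomputed sums,
// by enumerating the unconstrained solution, the four edge solutions and
// the corners of the (a, c) box.
static inline void solve_ac(double m, double Sx, double Sxx, double Sy,
                            double Sxy, double alo, double ahi, double clo,
                            double chi, double &a_out, double &c_out,
                            double &q_out) {
  // q(a, c) = a^2 Sxx + m c^2 + 2 a c Sx - 2 a Sxy - 2 c Sy  (rss - Syy)
  double best_q = std::numeric_limits<double>::infinity();
  double best_a = alo, best_c = clo;
  const double denom = m * Sxx - Sx * Sx;

  auto consider = [&](double a, double c) {
    if (a < alo) a = alo; else if (a > ahi) a = ahi;
    if (c < clo) c = clo; else if (c > chi) c = chi;
    double q = a * a * Sxx + m * c * c + 2.0 * a * c * Sx -
               2.0 * a * Sxy - 2.0 * c * Sy;
    if (q < best_q) { best_q = q; best_a = a; best_c = c; }
  };

  if (denom > 1e-12) {
    double a = (m * Sxy - Sx * Sy) / denom;
    double c = (Sy - a * Sx) / m;
    consider(a, c);
  }
  // edges: a fixed -> c = (Sy - a Sx) / m ; c fixed -> a = (Sxy - c Sx) / Sxx
  consider(alo, (Sy - alo * Sx) / m);
  consider(ahi, (Sy - ahi * Sx) / m);
  if (Sxx > 1e-12) {
    consider((Sxy - clo * Sx) / Sxx, clo);
    consider((Sxy - chi * Sx) / Sxx, chi);
  }
  consider(alo, clo); consider(alo, chi);
  consider(ahi, clo); consider(ahi, chi);

  a_out = best_a; c_out = best_c; q_out = best_q;
}

// Exhaustive grid search for the six-parameter reference-frame model
//   r = a exp(-(TX - mu)^2 / 2 s^2) (1 + g HE) + c,  TX = w TE + (1 - w) TH
// over regular grids in (w, mu, s, g), profiling (a, c) in closed form at
// every grid point under their box constraints.
// [[Rcpp::export(name = ".grid_search_rf")]]
List grid_search_rf(NumericVector y, NumericVector TE, NumericVector TH,
                    NumericVector HE, NumericVector w_grid,
                    NumericVector mu_grid, NumericVector s_grid,
                    NumericVector g_grid, NumericVector a_bounds,
                    NumericVector c_bounds) {
  const int n = y.size();
  const int nw = w_grid.size(), nmu = mu_grid.size(), ns = s_grid.size(),
            ng = g_grid.size();
  const double alo = a_bounds[0], ahi = a_bounds[1];
  const double clo = c_bounds[0], chi = c_bounds[1];

  double Sy = 0.0, Syy = 0.0;
  for (int i = 0; i < n; ++i) { Sy += y[i]; Syy += y[i] * y[i]; }

  std::vector<double> TX(n), G(n);
  double best_rss = std::numeric_limits<double>::infinity();
  double bw = w_grid[0], bmu = mu_grid[0], bs = s_grid[0], bg = g_grid[0];
  double ba = alo, bc = clo;

  for (int iw = 0; iw < nw; ++iw) {
    const double w = w_grid[iw];
    for (int i = 0; i < n; ++i) TX[i] = w * TE[i] + (1.0 - w) * TH[i];
    for (int is = 0; is < ns; ++is) {
      const double inv2s2 = 1.0 / (2.0 * s_grid[is] * s_grid[is]);
      for (int imu = 0; imu < nmu; ++imu) {
        const double mu = mu_grid[imu];
        // sums over the Gaussian factor and its HE-weighted versions
        double SG = 0, SGH = 0, SGG = 0, SGGH = 0, SGGHH = 0, SGy = 0,
               SGHy = 0;
        for (int i = 0; i < n; ++i) {
          const double d = TX[i] - mu;
          const double gi = std::exp(-d * d * inv2s2);
          G[i] = gi;
          const double gh = gi * HE[i];
          SG += gi; SGH += gh;
          SGG += gi * gi; SGGH += gi * gh; SGGHH += gh * gh;
          SGy += gi * y[i]; SGHy += gh * y[i];
        }
        for (int ig = 0; ig < ng; ++ig) {
          const double g = g_grid[ig];
          const double Sx = SG + g * SGH;
          const double Sxx = SGG + 2.0 * g * SGGH + g * g * SGGHH;
          const double Sxy = SGy + g * SGHy;
          double a, c, q;
          solve_ac((double)n, Sx, Sxx, Sy, Sxy, alo, ahi, clo, chi, a, c, q);
          const double rss = Syy + q;
          const bool better =
              rss < best_rss - 1e-12 ||
              (std::fabs(rss - best_rss) <= 1e-12 &&
               std::fabs(w - 0.5) < std::fabs(bw - 0.5));
          if (better) {
            best_rss = rss;
            bw = w; bmu = mu; bs = s_grid[is]; bg = g; ba = a; bc = c;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  if (best_rss < 0.0) best_rss = 0.0;
  return List::create(_["a"] = ba, _["mu"] = bmu, _["s"] = bs, _["g"] = bg,
                      _["c"] = bc, _["w"] = bw, _["rss"] = best_rss);
}
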