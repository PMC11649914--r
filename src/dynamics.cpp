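#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// portable positive modulo (avoids libm fmod)
static inline double wrap_len(double x, double L) {
  return x - std::floor(x / L) * L;
}

// Toy potential kinds (mirrors R-side potential_spec):
// 1 harmonic 1D: params = (kappa, x0)
// 2 double well 1D: params = (barrier, xm)  U = B((x/xm)^2 - 1)^2
// 3 periodic dihedral 1D: params = triples (A, n, phi), U = sum A(1+cos(n t - phi))
// 4 three-well 2D: params = 3 x (x, y, depth, sigma) then kconf
// 5 tabulated 1D: params = (xmin, dx, n, U_0..U_{n-1}), linear force interp

static inline void pot_grad(int kind, const NumericVector& par,
                            const double* x, int dim, double* g) {
  switch (kind) {
  case 1:
    g[0] = par[0] * (x[0] - par[1]);
    break;
  case 2: {
    double B = par[0], xm = par[1];
    double u = x[0] / xm;
    g[0] = 4.0 * B * u * (u * u - 1.0) / xm;
    break;
  }
  case 3: {
    double s = 0.0;
    for (int k = 0; k + 2 < par.size(); k += 3)
      s += -par[k] * par[k + 1] * std::sin(par[k + 1] * x[0] - par[k + 2]);
    g[0] = s;
    break;
  }
  case 4: {
    double gx = 0.0, gy = 0.0;
    for (int w = 0; w < 3; ++w) {
      double cx = par[4 * w], cy = par[4 * w + 1];
      double d = par[4 * w + 2], s2 = par[4 * w + 3] * par[4 * w + 3];
      double dx = x[0] - cx, dy = x[1] - cy;
      double e = d * std::exp(-(dx * dx + dy * dy) / (2.0 * s2)) / s2;
      gx += e * dx;
      gy += e * dy;
    }
    double kc = par[12];
    g[0] = gx + kc * x[0];
    g[1] = gy + kc * x[1];
    break;
  }
  case 5: {
    double xmin = par[0], dx = par[1];
    int n = (int)par[2];
    double u = (x[0] - xmin) / dx;
    int i = (int)std::floor(u);
    if (i < 0) i = 0;
    if (i > n - 2) i = n - 2;
    g[0] = (par[3 + i + 1] - par[3 + i]) / dx;
    break;
  }
  default:
    stop("unknown potential kind");
  }
}

// [[Rcpp::export(name = ".langevin_cpp")]]
NumericMatrix langevin_cpp(int kind, NumericVector params, int dim,
                           NumericVector x0, int n_steps, double dt,
                           double kT, double friction, int stride) {
  int n_save = n_steps / stride;
  NumericMatrix out(n_save, dim);
  double x[2], g[2];
  for (int d = 0; d < dim; ++d) x[d] = x0[d];
  double a = dt / friction;
  double b = std::sqrt(2.0 * kT * dt / friction);
  GetRNGstate();
  int k = 0;
  for (int s = 1; s <= n_steps; ++s) {
    pot_grad(kind, params, x, dim, g);
    for (int d = 0; d < dim; ++d) x[d] += -a * g[d] + b * norm_rand();
    if (kind == 3) {  // wrap periodic CV to [-pi, pi)
      x[0] = wrap_len(x[0] + M_PI, 2.0 * M_PI) - M_PI;
    }
    if (s % stride == 0 && k < n_save) {
      for (int d = 0; d < dim; ++d) out(k, d) = x[d];
      ++k;
    }
  }
  PutRNGstate();
  return out;
}

// Well-tempered metadynamics on a 1D CV with bias kept on a uniform grid.
// Returns the CV trajectory, the instantaneous bias V(s_t, t) and offset
// c(t) at every saved frame (Tiwary-Parrinello reweighting inputs), the
// final bias grid and the deposition history.
// [[Rcpp::export(name = ".wtmtd_cpp")]]
List wtmtd_cpp(int kind, NumericVector params, double x0, int n_steps,
               double dt, double kT, double friction, int stride,
               double w0, double sigma, double gamma, int dep_stride,
               double grid_min, double grid_max, int n_grid, bool periodic) {
  int n_save = n_steps / stride;
  NumericVector cv(n_save), v_frame(n_save), c_frame(n_save);
  NumericVector bias(n_grid), grid(n_grid);
  double dgrid = (grid_max - grid_min) / (n_grid - 1);
  for (int i = 0; i < n_grid; ++i) grid[i] = grid_min + i * dgrid;
  double L = grid_max - grid_min;

  std::vector<double> dep_center, dep_height, dep_time;
  double x = x0, g;
  double a = dt / friction;
  double bnoise = std::sqrt(2.0 * kT * dt / friction);
  double c_now = 0.0;

  // linear interpolation of the bias and its gradient on the grid
  auto bias_at = [&](double s, double* grad) {
    double u = (s - grid_min) / dgrid;
    int i = (int)std::floor(u);
    if (i < 0) i = 0;
    if (i > n_grid - 2) i = n_grid - 2;
    double f = u - i;
    if (grad) *grad = (bias[i + 1] - bias[i]) / dgrid;
    return bias[i] * (1 - f) + bias[i + 1] * f;
  };

  GetRNGstate();
  int k = 0;
  for (int s = 1; s <= n_steps; ++s) {
    pot_grad(kind, params, &x, 1, &g);
    double gb;
    bias_at(x, &gb);
    x += -a * (g + gb) + bnoise * norm_rand();
    if (periodic) {
      x = wrap_len(x - grid_min, L) + grid_min;
    } else {
      if (x < grid_min) x = 2 * grid_min - x;   // reflecting walls
      if (x > grid_max) x = 2 * grid_max - x;
    }
    if (s % dep_stride == 0) {
      double v_here = bias_at(x, nullptr);
      double h = w0 * std::exp(-v_here / ((gamma - 1.0) * kT));
      for (int i = 0; i < n_grid; ++i) {
        double d = grid[i] - x;
        if (periodic) {
          d = wrap_len(d + 0.5 * L, L) - 0.5 * L;
        }
        bias[i] += h * std::exp(-d * d / (2.0 * sigma * sigma));
      }
      dep_center.push_back(x);
      dep_height.push_back(h);
      dep_time.push_back(s * dt);
      // c(t) = kT * ln( sum exp(g/(g-1) V/kT) / sum exp(1/(g-1) V/kT) )
      double m = 0.0;
      for (int i = 0; i < n_grid; ++i) if (bias[i] > m) m = bias[i];
      double num = 0.0, den = 0.0;
      double fg = gamma / (gamma - 1.0), f1 = 1.0 / (gamma - 1.0);
      for (int i = 0; i < n_grid; ++i) {
        num += std::exp(fg * (bias[i] - m) / kT);
        den += std::exp(f1 * (bias[i] - m) / kT);
      }
      c_now = m + kT * std::log(num / den);
    }
    if (s % stride == 0 && k < n_save) {
      cv[k] = x;
      v_frame[k] = bias_at(x, nullptr);
      c_frame[k] = c_now;
      ++k;
    }
  }
  PutRNGstate();
  return List::create(_["cv"] = cv, _["v_frame"] = v_frame,
                      _["c_frame"] = c_frame, _["grid"] = grid,
                      _["bias_grid"] = bias,
                      _["dep_center"] = wrap(dep_center),
                      _["dep_height"] = wrap(dep_height),
                      _["dep_time"] = wrap(dep_time));
}
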