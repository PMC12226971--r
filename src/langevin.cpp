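#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) integrator for the analytic toy
// potentials. Noise is pre-generated in R (N(0,1)) so all randomness flows
// through R's RNG and a single seed.
//
// form 0: harmonic        U = 0.5 * kappa * |x - center|^2        (any dim)
// form 1: double_well_1d  U = h * (x^2 - 1)^2                      (1D)
// form 2: triple_well_2d  U = -sum_j h_j exp(-|x-w_j|^2/(2 s^2))
//                             + 0.5 * c * |x|^2                    (2D)

static inline void grad_harmonic(const double* x, double* g, int dim,
                                 const double* center, double kappa) {
  for (int d = 0; d < dim; ++d) g[d] = kappa * (x[d] - center[d]);
}

static inline void grad_double_well(const double* x, double* g, double h) {
  g[0] = 4.0 * h * x[0] * (x[0] * x[0] - 1.0);
}

static inline void grad_triple_well(const double* x, double* g,
                                    const NumericMatrix& wells,
                                    const NumericVector& depths,
                                    double sigma2, double confine) {
  g[0] = confine * x[0];
  g[1] = confine * x[1];
  for (int j = 0; j < wells.nrow(); ++j) {
    double dx = x[0] - wells(j, 0);
    double dy = x[1] - wells(j, 1);
    double e = depths[j] * std::exp(-(dx * dx + dy * dy) / (2.0 * sigma2));
    g[0] += e * dx / sigma2;
    g[1] += e * dy / sigma2;
  }
}

// [[Rcpp::export(name = ".langevin_integrate")]]
NumericMatrix langevin_integrate(int form, List params, NumericVector x0,
                                 NumericMatrix noise, double step, double kT,
                                 int stride, double bound) {
  const int n_steps = noise.nrow();
  const int dim = x0.size();
  if (noise.ncol() != dim) stop("noise dimension mismatch");
  const int n_save = n_steps / stride;
  NumericMatrix out(n_save, dim);

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> g(dim);
  const double amp = std::sqrt(2.0 * kT * step);

  NumericMatrix wells;
  NumericVector depths, center;
  double kappa = 0, h = 0, sigma2 = 1, confine = 0;
  if (form == 0) {
    center = params["center"];
    kappa = as<double>(params["kappa"]);
    if (center.size() != dim) stop("harmonic center dimension mismatch");
  } else if (form == 1) {
    h = as<double>(params["barrier"]);
    if (dim != 1) stop("double_well_1d is one-dimensional");
  } else if (form == 2) {
    wells = as<NumericMatrix>(params["wells"]);
    depths = params["depths"];
    double s = as<double>(params["sigma"]);
    sigma2 = s * s;
    confine = as<double>(params["confinement"]);
    if (dim != 2) stop("triple_well_2d is two-dimensional");
  } else {
    stop("unknown potential form");
  }

  int save_row = 0;
  for (int t = 0; t < n_steps; ++t) {
    if (form == 0) grad_harmonic(x.data(), g.data(), dim, center.begin(), kappa);
    else if (form == 1) grad_double_well(x.data(), g.data(), h);
    else grad_triple_well(x.data(), g.data(), wells, depths, sigma2, confine);

    for (int d = 0; d < dim; ++d) {
      x[d] += -g[d] * step + amp * noise(t, d);
      if (!(std::fabs(x[d]) < bound)) {
        stop("trajectory diverged (|x| > %.1f) at step %d; use a smaller step_size",
             bound, t + 1);
      }
    }
    if ((t + 1) % stride == 0) {
      for (int d = 0; d < dim; ++d) out(save_row, d) = x[d];
      ++save_row;
    }
  }
  return out;
}
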