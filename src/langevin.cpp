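#include <Rcpp.h>
using namespace Rcpp;

// Unit system: kcal/mol, Angstrom, ps, amu.
// 1 kcal/mol = 418.4 amu A^2 / ps^2, so accelerations from forces in
// kcal/mol/A need this factor to come out in A/ps^2.
static const double F_CONV = 418.4;

static inline double poly_v(const std::vector<double> &c, double x) {
  // Horner, c[i] is the coefficient of x^i
  double v = 0.0;
  for (int i = (int)c.size() - 1; i >= 0; --i) v = v * x + c[i];
  return v;
}

static inline double poly_dv(const std::vector<double> &c, double x) {
  double d = 0.0;
  for (int i = (int)c.size() - 1; i >= 1; --i) d = d * x + i * c[i];
  return d;
}

static inline void reflect(double &x, double &v, double lo, double hi) {
  // reflecting walls; loop handles the (rare) multi-bounce case
  for (int it = 0; it < 64 && (x < lo || x > hi); ++it) {
    if (x < lo) { x = 2.0 * lo - x; v = -v; }
    if (x > hi) { x = 2.0 * hi - x; v = -v; }
  }
}

//' @title Langevin (BAOAB) kernel for 1D polynomial potentials
//' @description Internal compiled integrator. Propagates a single particle in
//'   a polynomial potential with reflecting walls, optionally under a frozen
//'   harmonic boost (E, k), recording frames every \code{record_stride} steps
//'   and accumulating Welford statistics of the unboosted potential at every
//'   step. Uses R's RNG, so results are reproducible under \code{set.seed()}.
//' @keywords internal
// [[Rcpp::export]]
List cpp_langevin_poly(NumericVector coef, double lo, double hi,
                       double x0, double v0, double mass,
                       double dt, double friction, double kT,
                       int n_steps, int record_stride,
                       bool boost, double E, double k) {
  std::vector<double> c(coef.begin(), coef.end());
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double sigma_v = std::sqrt(kT * F_CONV / mass);

  int n_rec = (record_stride > 0) ? n_steps / record_stride : 0;
  NumericVector xr(n_rec), vr(n_rec), vr_pot(n_rec), vr_dv(n_rec);

  double x = x0, v = v0;
  // Welford accumulators over the unboosted potential, every step
  double w_n = 0.0, w_mean = 0.0, w_m2 = 0.0;
  double w_min = R_PosInf, w_max = R_NegInf;

  double V = poly_v(c, x);
  double fb = (boost && V < E) ? (1.0 - k * (E - V)) : 1.0;
  double F = -poly_dv(c, x) * fb;
  int irec = 0;

  for (int step = 1; step <= n_steps; ++step) {
    v += 0.5 * dt * F / mass * F_CONV;
    x += 0.5 * dt * v;
    reflect(x, v, lo, hi);
    v = c1 * v + c2 * sigma_v * norm_rand();
    x += 0.5 * dt * v;
    reflect(x, v, lo, hi);
    V = poly_v(c, x);
    fb = (boost && V < E) ? (1.0 - k * (E - V)) : 1.0;
    F = -poly_dv(c, x) * fb;
    v += 0.5 * dt * F / mass * F_CONV;

    w_n += 1.0;
    double d = V - w_mean;
    w_mean += d / w_n;
    w_m2 += d * (V - w_mean);
    if (V < w_min) w_min = V;
    if (V > w_max) w_max = V;

    if (record_stride > 0 && step % record_stride == 0 && irec < n_rec) {
      xr[irec] = x;
      vr[irec] = v;
      vr_pot[irec] = V;
      vr_dv[irec] = (boost && V < E) ? 0.5 * k * (E - V) * (E - V) : 0.0;
      ++irec;
    }
  }

  return List::create(
    _["x"] = xr, _["v"] = vr, _["V"] = vr_pot, _["dV"] = vr_dv,
    _["x_final"] = x, _["v_final"] = v,
    _["stat_n"] = w_n, _["stat_mean"] = w_mean, _["stat_m2"] = w_m2,
    _["stat_min"] = w_min, _["stat_max"] = w_max);
}
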