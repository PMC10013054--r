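// Adaptive Dormand-Prince 5(4) integration of a network of FitzHugh-Nagumo
// oscillators with rotational (cross) coupling and an external input applied
// through a node mask.  The hot loop lives here because a 90-node network
// integrated over 1e4-1e5 dimensionless time units at slow-fast step sizes is
// far beyond what an R-level right-hand side can sustain.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct FhnSystem {
  int n;                 // nodes
  const double* M;       // n x n combined coupling weights (column-major,
                         // symmetric: column k == row k)
  std::vector<double> deg;  // row sums of M
  double buu, buv, bvu, bvv;
  double eps, a;
  const double* ck;      // input mask per node
  const double* inp;     // zero-order-hold input samples (may be null)
  int n_inp;
  double inp_dt;         // sim-time spacing of input samples
  double inp_t0;         // sim time at which the input starts

  double input_at(double t) const {
    if (n_inp == 0 || t < inp_t0) return 0.0;
    int idx = static_cast<int>((t - inp_t0) / inp_dt);
    if (idx < 0 || idx >= n_inp) return 0.0;
    return inp[idx];
  }

  // dy = f(t, y), y = (u_1..u_n, v_1..v_n)
  void rhs(double t, const double* y, double* dy) const {
    const double* u = y;
    const double* v = y + n;
    const double I = input_at(t);
    for (int k = 0; k < n; ++k) {
      double cu = 0.0, cv = 0.0;
      const double* mk = M + static_cast<size_t>(n) * k;  // column k (== row k)
      for (int j = 0; j < n; ++j) {
        cu += mk[j] * u[j];
        cv += mk[j] * v[j];
      }
      const double su = cu - deg[k] * u[k];
      const double sv = cv - deg[k] * v[k];
      const double uk = u[k];
      dy[k] = (uk - uk * uk * uk / 3.0 - v[k] + buu * su + buv * sv +
               ck[k] * I) / eps;
      dy[n + k] = uk + a + bvu * su + bvv * sv;
    }
  }
};

// Dormand-Prince coefficients
const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
const double A21 = 1.0 / 5;
const double A31 = 3.0 / 40, A32 = 9.0 / 40;
const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187, A53 = 64448.0 / 6561,
             A54 = -212.0 / 729;
const double A61 = 9017.0 / 3168, A62 = -355.0 / 33, A63 = 46732.0 / 5247,
             A64 = 49.0 / 176, A65 = -5103.0 / 18656;
const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
             B5 = -2187.0 / 6784, B6 = 11.0 / 84;
// embedded 4th-order weights
const double E1 = 5179.0 / 57600, E3 = 7571.0 / 16695, E4 = 393.0 / 640,
             E5 = -92097.0 / 339200, E6 = 187.0 / 2100, E7 = 1.0 / 40;

}  // namespace

// [[Rcpp::export(name = ".fhn_rhs_eval")]]
NumericVector fhn_rhs_eval(double t, NumericVector y, NumericMatrix M,
                           double buu, double buv, double bvu, double bvv,
                           double eps, double a, NumericVector ck,
                           NumericVector input, double input_dt,
                           double input_t0) {
  FhnSystem sys;
  sys.n = M.nrow();
  sys.M = M.begin();
  sys.deg.assign(sys.n, 0.0);
  for (int k = 0; k < sys.n; ++k)
    for (int j = 0; j < sys.n; ++j) sys.deg[k] += M(k, j);
  sys.buu = buu; sys.buv = buv; sys.bvu = bvu; sys.bvv = bvv;
  sys.eps = eps; sys.a = a;
  sys.ck = ck.begin();
  sys.inp = input.size() ? input.begin() : nullptr;
  sys.n_inp = input.size();
  sys.inp_dt = input_dt;
  sys.inp_t0 = input_t0;
  NumericVector dy(2 * sys.n);
  sys.rhs(t, y.begin(), dy.begin());
  return dy;
}

// Integrate from t0 to the last output time, storing the state at out_times
// (strictly increasing, first >= t0).  Steps are clamped so that every output
// time is hit exactly; with slow-fast FHN dynamics the adaptive step is
// normally much smaller than the output spacing.
// [[Rcpp::export(name = ".fhn_integrate")]]
List fhn_integrate(NumericVector y0, double t0, NumericVector out_times,
                   NumericMatrix M, double buu, double buv, double bvu,
                   double bvv, double eps, double a, NumericVector ck,
                   NumericVector input, double input_dt, double input_t0,
                   double rtol, double atol, double h_init, double h_max,
                   double max_steps) {
  const int n = M.nrow();
  const int nv = 2 * n;
  if (y0.size() != nv) stop("state dimension must be 2 * n_nodes");

  FhnSystem sys;
  sys.M = M.begin();
  sys.n = n;
  sys.deg.assign(n, 0.0);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j) sys.deg[k] += M(k, j);
  sys.buu = buu; sys.buv = buv; sys.bvu = bvu; sys.bvv = bvv;
  sys.eps = eps; sys.a = a;
  sys.ck = ck.begin();
  sys.inp = input.size() ? input.begin() : nullptr;
  sys.n_inp = input.size();
  sys.inp_dt = input_dt;
  sys.inp_t0 = input_t0;

  const int n_out = out_times.size();
  NumericMatrix out(n_out, nv);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(nv), k2(nv), k3(nv), k4(nv), k5(nv), k6(nv), k7(nv),
      ytmp(nv), ynew(nv);

  double t = t0;
  double h = h_init;
  int iout = 0;
  long n_acc = 0, n_rej = 0;
  const double t_end = out_times[n_out - 1];

  // emit any output times equal to t0
  while (iout < n_out && out_times[iout] <= t0) {
    for (int i = 0; i < nv; ++i) out(iout, i) = y[i];
    ++iout;
  }

  sys.rhs(t, y.data(), k1.data());  // FSAL seed
  long steps = 0;
  while (t < t_end && iout < n_out) {
    if (++steps > static_cast<long>(max_steps))
      stop("fhn integrator exceeded max_steps (%g) at t = %g", max_steps, t);
    if (h > h_max) h = h_max;
    double t_next_out = out_times[iout];
    bool hit_out = false;
    if (t + h >= t_next_out) {
      h = t_next_out - t;
      hit_out = true;
    }

    for (int i = 0; i < nv; ++i) ytmp[i] = y[i] + h * A21 * k1[i];
    sys.rhs(t + C2 * h, ytmp.data(), k2.data());
    for (int i = 0; i < nv; ++i)
      ytmp[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    sys.rhs(t + C3 * h, ytmp.data(), k3.data());
    for (int i = 0; i < nv; ++i)
      ytmp[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    sys.rhs(t + C4 * h, ytmp.data(), k4.data());
    for (int i = 0; i < nv; ++i)
      ytmp[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                            A54 * k4[i]);
    sys.rhs(t + C5 * h, ytmp.data(), k5.data());
    for (int i = 0; i < nv; ++i)
      ytmp[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                            A64 * k4[i] + A65 * k5[i]);
    sys.rhs(t + h, ytmp.data(), k6.data());
    for (int i = 0; i < nv; ++i)
      ynew[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                            B5 * k5[i] + B6 * k6[i]);
    sys.rhs(t + h, ynew.data(), k7.data());

    // scaled RMS error of (5th - 4th) order solutions
    double err = 0.0;
    for (int i = 0; i < nv; ++i) {
      const double e5 = y[i] + h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] +
                                    E5 * k5[i] + E6 * k6[i] + E7 * k7[i]);
      const double sc =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double d = (ynew[i] - e5) / sc;
      err += d * d;
    }
    err = std::sqrt(err / nv);
    if (!std::isfinite(err))
      stop("fhn integrator produced a non-finite state at t = %g", t);

    if (err <= 1.0) {
      t += h;
      y.swap(ynew);
      k1.swap(k7);  // FSAL
      ++n_acc;
      if (hit_out) {
        for (int i = 0; i < nv; ++i) out(iout, i) = y[i];
        ++iout;
        // emit duplicates (should not normally occur)
        while (iout < n_out && out_times[iout] <= t) {
          for (int i = 0; i < nv; ++i) out(iout, i) = y[i];
          ++iout;
        }
      }
    } else {
      ++n_rej;
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-12)
      stop("fhn integrator step size underflow at t = %g", t);
  }

  return List::create(_["states"] = out, _["n_accepted"] = (double)n_acc,
                      _["n_rejected"] = (double)n_rej);
}
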