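#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step explicit Euler integration of the built-in growth-division toy
// model.  State layout: V (cell size), A (START activator), B (S/G2/M
// activity), E (EXIT effector), Z (EXIT-driven clearance factor), then any
// number of pure reporter species each first-order driven by A, B or E.
//
// `core` parameter order (kept in sync with .toy_core_order in R):
//   mu, ks_a, ks_a2, kd_a, ki_ae, ki_az, ks_b, kd_b, Ka,
//   ks_e, kd_e, Kb, ks_z, kd_z, h, theta_hi, theta_lo, f
//
// Division: hysteresis on E.  The trigger arms when E >= theta_hi and fires
// at the first grid point where an armed E drops below theta_lo (downward
// threshold crossing).  The division map V -> f*V is applied at that grid
// point, before the next Euler step.  The stored grid state is therefore the
// post-division state; the recorded division size is the pre-division V.

static inline double hill(double x, double K, double h) {
  if (x <= 0.0) return 0.0;
  double xh = std::pow(x, h);
  return xh / (std::pow(K, h) + xh);
}

// [[Rcpp::export]]
List cpp_toy_simulate(NumericVector init, NumericVector core,
                      NumericVector rep_ks, NumericVector rep_kd,
                      IntegerVector rep_driver, double dt, int nsteps,
                      bool keep_states) {
  const int n_rep = rep_ks.size();
  const int S = 5 + n_rep;
  if (init.size() != S) stop("init length does not match species count");

  const double mu = core[0], ks_a = core[1], ks_a2 = core[2], kd_a = core[3],
               ki_ae = core[4], ki_az = core[5], ks_b = core[6],
               kd_b = core[7], Ka = core[8], ks_e = core[9], kd_e = core[10],
               Kb = core[11], ks_z = core[12], kd_z = core[13], h = core[14],
               theta_hi = core[15], theta_lo = core[16], f = core[17];

  const double BLOWUP_CAP = 1e12;

  std::vector<double> x(init.begin(), init.end());
  std::vector<double> dx(S);
  std::vector<double> sum(S, 0.0);
  NumericMatrix states;
  if (keep_states) states = NumericMatrix(nsteps + 1, S);

  std::vector<double> div_time, div_size;
  std::vector<double> post_last(S);
  bool have_post_last = false;

  bool armed = x[3] >= theta_hi;
  double max_size = x[0];
  bool blowup = false;
  double blowup_time = NA_REAL;
  int n_grid = 0;

  for (int k = 0; k <= nsteps; ++k) {
    const double t = k * dt;

    // event detection on the current grid state (pre-division value of V)
    if (x[0] > max_size) max_size = x[0];
    if (!armed && x[3] >= theta_hi) armed = true;
    if (armed && x[3] < theta_lo && k > 0) {
      div_time.push_back(t);
      div_size.push_back(x[0]);
      x[0] *= f;
      armed = false;
      for (int s = 0; s < S; ++s) post_last[s] = x[s];
      have_post_last = true;
    }

    // store post-division grid state
    if (keep_states) for (int s = 0; s < S; ++s) states(k, s) = x[s];
    for (int s = 0; s < S; ++s) sum[s] += x[s];
    ++n_grid;

    if (k == nsteps) break;

    // Euler step
    dx[0] = mu * x[0];
    dx[1] = (ks_a + ks_a2) * x[0] - kd_a * x[1]
            - (ki_ae * x[3] + ki_az * x[4]) * x[1];
    dx[2] = ks_b * hill(x[1], Ka, h) - kd_b * x[2];
    dx[3] = ks_e * hill(x[2], Kb, h) - kd_e * x[3];
    dx[4] = ks_z * x[3] - kd_z * x[4];
    for (int r = 0; r < n_rep; ++r)
      dx[5 + r] = rep_ks[r] * x[rep_driver[r]] - rep_kd[r] * x[5 + r];

    bool bad = false;
    for (int s = 0; s < S; ++s) {
      x[s] += dt * dx[s];
      if (!std::isfinite(x[s]) || std::fabs(x[s]) > BLOWUP_CAP) bad = true;
    }
    if (bad) {
      blowup = true;
      blowup_time = (k + 1) * dt;
      break;
    }
  }

  NumericVector means(S), final_state(S), post_last_div(S);
  for (int s = 0; s < S; ++s) {
    means[s] = sum[s] / n_grid;
    final_state[s] = x[s];
    post_last_div[s] = have_post_last ? post_last[s] : NA_REAL;
  }

  List out = List::create(
      _["div_time"] = wrap(div_time), _["div_size"] = wrap(div_size),
      _["max_size"] = max_size, _["means"] = means,
      _["final_state"] = final_state, _["post_last_div"] = post_last_div,
      _["n_grid"] = n_grid, _["blowup"] = blowup,
      _["blowup_time"] = blowup_time);
  if (keep_states) {
    if (blowup) {
      // truncate the grid to the points actually computed
      NumericMatrix kept(n_grid, S);
      for (int k = 0; k < n_grid; ++k)
        for (int s = 0; s < S; ++s) kept(k, s) = states(k, s);
      out["states"] = kept;
    } else {
      out["states"] = states;
    }
  }
  return out;
}

// Round each value to the nearest IEEE 754 single-precision representable
// number, returned at double precision.  Idempotent by construction.
// [[Rcpp::export]]
NumericVector cpp_truncate32(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    if (ISNAN(v)) { out[i] = v; continue; }
    float t = static_cast<float>(v);
    if (std::isfinite(v) && !std::isfinite(static_cast<double>(t)))
      stop("value overflows single precision");
    out[i] = static_cast<double>(t);
  }
  out.attr("names") = x.attr("names");
  return out;
}
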