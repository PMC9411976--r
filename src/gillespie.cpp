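#include <Rcpp.h>
using namespace Rcpp;

// Exact Doob-Gillespie simulation of the four-state activation model with a
// time-varying forward propensity. Within each protocol segment the LPS
// level decays monotonically, so the activation propensity evaluated with
// the level at the current time bounds it over the whole waiting interval;
// candidate event times from the bounding rate are thinned (Ogata-style
// rejection), which samples the inhomogeneous process exactly.
//
// Reactions (single-cell moves, total count conserved):
//   N  -> P    at N * alpha * (1 + mu * L(t))
//   P  -> N    at beta   * P
//   P  -> NR   at gamma1 * P
//   NR -> N    at beta2  * NR
//   NR -> NRPS at gamma2 * NR
//
// Times are in days. `segments` has columns t0, t1, L0 (level at entry).
// Reported states are the jump-process values just before each grid time.
// Uses R's RNG, so set.seed() on the R side governs reproducibility.

// [[Rcpp::export]]
List norm_gillespie_cpp(NumericVector rates, NumericMatrix segments,
                        IntegerVector init, NumericVector report_d) {
  const double alpha = rates[0], beta = rates[1], beta2 = rates[2],
               gamma1 = rates[3], gamma2 = rates[4], mu = rates[5],
               delta = rates[6];
  int N = init[0], P = init[1], NR = init[2], NRPS = init[3];
  const int n_rep = report_d.size();
  IntegerMatrix out(n_rep, 4);
  int rep_i = 0;
  long long n_events = 0;
  RNGScope scope;

  auto record_until = [&](double t_now) {
    while (rep_i < n_rep && report_d[rep_i] <= t_now) {
      out(rep_i, 0) = N; out(rep_i, 1) = P;
      out(rep_i, 2) = NR; out(rep_i, 3) = NRPS;
      ++rep_i;
    }
  };

  for (int s = 0; s < segments.nrow(); ++s) {
    const double t0 = segments(s, 0), t1 = segments(s, 1), L0 = segments(s, 2);
    double t = t0;
    while (t < t1) {
      const double L_now = L0 * std::exp(-delta * (t - t0));
      const double a_fwd_max = N * alpha * (1.0 + mu * L_now);
      const double a_const = (beta + gamma1) * P + (beta2 + gamma2) * NR;
      const double B = a_fwd_max + a_const;
      if (B <= 0.0) { t = t1; break; }
      const double tau = R::exp_rand() / B;
      const double t_cand = t + tau;
      if (t_cand >= t1) { record_until(t1 - 1e-15); t = t1; break; }
      record_until(t_cand - 1e-15);
      t = t_cand;
      const double L_t = L0 * std::exp(-delta * (t - t0));
      const double a_fwd = N * alpha * (1.0 + mu * L_t);
      const double a_tot = a_fwd + a_const;
      if (unif_rand() * B > a_tot) continue;  // thinned candidate
      double u = unif_rand() * a_tot;
      if (u < a_fwd) { --N; ++P; }
      else if (u < a_fwd + beta * P) { --P; ++N; }
      else if (u < a_fwd + (beta + gamma1) * P) { --P; ++NR; }
      else if (u < a_fwd + (beta + gamma1) * P + beta2 * NR) { --NR; ++N; }
      else { --NR; ++NRPS; }
      ++n_events;
    }
    record_until(t1 - 1e-15);
  }
  // grid times at or beyond the final segment end get the final state
  while (rep_i < n_rep) {
    out(rep_i, 0) = N; out(rep_i, 1) = P;
    out(rep_i, 2) = NR; out(rep_i, 3) = NRPS;
    ++rep_i;
  }
  return List::create(_["states"] = out, _["n_events"] = (double)n_events);
}
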