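#include <Rcpp.h>
using namespace Rcpp;

// Exact (Gillespie) simulation of a single-cell lineage: telegraph
// transcription per cell-cycle stage, instantaneous gene duplication on
// entering S2 (both copies OFF), and binomial partitioning of transcripts
// at division, after which the lineage follows one daughter. Uses R's RNG
// so set.seed() makes runs byte-reproducible.
//
// Per completed cycle we accumulate the time-weighted sums of 1, M and M^2
// separately for the S1 and S2 portions; the R wrapper turns these into
// stage-conditioned moment estimates with batch-mean standard errors.

// [[Rcpp::export(name = ".simulate_lineage_cpp")]]
List simulate_lineage_cpp(double l1, double g1, double v1, double d1,
                          double l2, double g2, double v2, double d2,
                          double k1, double k2,
                          double t_max, int max_cycles,
                          bool record_events) {
  std::vector<double> cyc_t1, cyc_t2, cyc_m1, cyc_m2, cyc_q1, cyc_q2;
  std::vector<double> m_before, m_after;
  std::vector<double> ev_t, ev_wait;
  std::vector<int> ev_stage, ev_i, ev_m;

  int U = 1, I = 0;
  double M = 0.0, t = 0.0;
  // accumulators for the cycle in progress
  double t1 = 0, t2 = 0, s1m = 0, s2m = 0, s1q = 0, s2q = 0;
  int cycles = 0;

  while (t < t_max && cycles < max_cycles) {
    double a[5];
    if (U == 1) {
      a[0] = l1 * (1 - I); a[1] = g1 * I; a[2] = v1 * I;
      a[3] = d1 * M;       a[4] = k1;
    } else {
      a[0] = l2 * (2 - I); a[1] = g2 * I; a[2] = v2 * I;
      a[3] = d2 * M;       a[4] = k2;
    }
    double a0 = a[0] + a[1] + a[2] + a[3] + a[4];
    if (!R_finite(a0) || a0 <= 0.0)
      stop("non-finite or non-positive total propensity");
    double wait = exp_rand() / a0;
    double dt = std::min(wait, t_max - t);
    if (U == 1) { t1 += dt; s1m += M * dt; s1q += M * M * dt; }
    else        { t2 += dt; s2m += M * dt; s2q += M * M * dt; }
    t += wait;
    if (t >= t_max) break;

    double u = unif_rand() * a0, acc = 0.0;
    int r = 4;
    for (int j = 0; j < 5; ++j) { acc += a[j]; if (u <= acc) { r = j; break; } }
    switch (r) {
      case 0: ++I; break;           // activation of one OFF copy
      case 1: --I; break;           // inactivation of one ON copy
      case 2: M += 1.0; break;      // synthesis
      case 3: M -= 1.0; break;      // degradation
      case 4:                       // stage transition
        if (U == 1) {               // duplication: enter S2, both copies OFF
          U = 2; I = 0;
        } else {                    // division: thin transcripts, back to S1
          m_before.push_back(M);
          M = R::rbinom(M, 0.5);
          m_after.push_back(M);
          U = 1; I = 0;
          cyc_t1.push_back(t1); cyc_t2.push_back(t2);
          cyc_m1.push_back(s1m); cyc_m2.push_back(s2m);
          cyc_q1.push_back(s1q); cyc_q2.push_back(s2q);
          t1 = t2 = s1m = s2m = s1q = s2q = 0.0;
          ++cycles;
        }
        break;
    }
    if (record_events) {
      ev_t.push_back(t); ev_wait.push_back(wait * a0);
      ev_stage.push_back(U); ev_i.push_back(I);
      ev_m.push_back((int) M);
    }
  }

  List out = List::create(
    _["cycles"] = DataFrame::create(
      _["time_s1"] = cyc_t1, _["time_s2"] = cyc_t2,
      _["int_m_s1"] = cyc_m1, _["int_m_s2"] = cyc_m2,
      _["int_m2_s1"] = cyc_q1, _["int_m2_s2"] = cyc_q2,
      _["m_before_division"] = m_before, _["m_after_division"] = m_after),
    _["n_cycles"] = cycles,
    _["t_end"] = std::min(t, t_max));
  if (record_events) {
    out["events"] = DataFrame::create(
      _["t"] = ev_t, _["stage"] = ev_stage, _["active"] = ev_i,
      _["mrna"] = ev_m, _["scaled_wait"] = ev_wait);
  }
  return out;
}
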