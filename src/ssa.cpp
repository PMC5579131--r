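#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct-method simulation of a mass-action network for an
// ensemble of independent cells. Reactions are encoded by up to two
// reactant species indices (i1, i2; 0 = absent, 1-based otherwise) and a
// dense net-change matrix. States are recorded at the requested times with
// last-event hold. Uses R's RNG stream, so set.seed() governs results.
//
// x0:     N x n initial copy numbers (non-negative integers as doubles)
// times:  strictly increasing recording times; simulation starts at times[0]
// returns N x n x T array
// [[Rcpp::export]]
NumericVector ssa_ensemble_cpp(NumericMatrix x0, IntegerVector i1,
                               IntegerVector i2, NumericVector rates,
                               IntegerMatrix net_change,
                               NumericVector times) {
  const int N = x0.nrow(), n = x0.ncol();
  const int nr = rates.size(), nt = times.size();
  NumericVector out(Dimension(N, n, nt));
  std::vector<double> x(n), a(nr);

  for (int cell = 0; cell < N; ++cell) {
    if (cell % 64 == 0) Rcpp::checkUserInterrupt();
    for (int s = 0; s < n; ++s) x[s] = x0(cell, s);
    double t = times[0];
    int rec = 0;
    // record the initial state at times[0]
    for (int s = 0; s < n; ++s) out[cell + N * (s + (R_xlen_t)n * rec)] = x[s];
    rec = 1;

    while (rec < nt) {
      double a0 = 0.0;
      for (int j = 0; j < nr; ++j) {
        double aj = rates[j];
        int s1 = i1[j], s2 = i2[j];
        if (s1 > 0) {
          aj *= x[s1 - 1];
          if (s2 > 0) {
            if (s2 == s1) aj *= 0.5 * (x[s1 - 1] - 1.0);
            else aj *= x[s2 - 1];
          }
        }
        if (aj < 0) aj = 0;
        a[j] = aj;
        a0 += aj;
      }
      if (a0 <= 0) {
        // frozen state: hold for all remaining recording times
        for (; rec < nt; ++rec)
          for (int s = 0; s < n; ++s)
            out[cell + N * (s + (R_xlen_t)n * rec)] = x[s];
        break;
      }
      double u = unif_rand();
      while (u <= 0.0) u = unif_rand();
      double tau = -std::log(u) / a0;
      double t_next = t + tau;
      while (rec < nt && times[rec] <= t_next) {
        for (int s = 0; s < n; ++s)
          out[cell + N * (s + (R_xlen_t)n * rec)] = x[s];
        ++rec;
      }
      if (rec >= nt) break;
      t = t_next;
      double target = unif_rand() * a0, acc = 0.0;
      int j = 0;
      for (; j < nr - 1; ++j) {
        acc += a[j];
        if (acc >= target) break;
      }
      for (int s = 0; s < n; ++s) x[s] += net_change(j, s);
    }
  }
  return out;
}
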