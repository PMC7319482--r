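#include <Rcpp.h>
using namespace Rcpp;

// Forward-project the size-structured population over one dawn-to-dawn
// window. Per 10-min step and subpopulation, a cell in class i (0-based)
// may grow into class i+1 (probability gam(t,s)), divide into class i-p
// (probability delta(i,s), producing two cells), or remain. The top class
// retains its growth fraction; classes i < p cannot divide (delta must be
// zero there, enforced by the caller).
//
// w0:        m x s matrix of initial expected cells per class (subpop cols)
// gam:       nsteps x s per-step growth probabilities
// delta:     m x s per-class division probabilities
// p:         classes per volume doubling (division drops a cell p classes)
// obs_steps: sorted 0-based step counts at which to record mixture
//            proportions (0 = initial state, nsteps = final state)
//
// Returns hourly mixture proportion matrix q (length(obs_steps) x m),
// total cells at start/end, and per-subpopulation start/end totals.
// [[Rcpp::export]]
List cpp_project(NumericMatrix w0, NumericMatrix gam, NumericMatrix delta,
                 int p, IntegerVector obs_steps) {
  const int m = w0.nrow();
  const int s = w0.ncol();
  const int nsteps = gam.nrow();
  const int nobs = obs_steps.size();

  NumericMatrix q(nobs, m);
  NumericMatrix w = clone(w0);
  NumericVector neww(m);

  NumericVector nsub_start(s), nsub_end(s);
  for (int j = 0; j < s; ++j)
    for (int i = 0; i < m; ++i) nsub_start[j] += w(i, j);

  int next_obs = 0;
  for (int t = 0; t <= nsteps; ++t) {
    while (next_obs < nobs && obs_steps[next_obs] == t) {
      double tot = 0.0;
      for (int j = 0; j < s; ++j)
        for (int i = 0; i < m; ++i) tot += w(i, j);
      for (int i = 0; i < m; ++i) {
        double wi = 0.0;
        for (int j = 0; j < s; ++j) wi += w(i, j);
        q(next_obs, i) = wi / tot;
      }
      ++next_obs;
    }
    if (t == nsteps) break;
    for (int j = 0; j < s; ++j) {
      const double g = gam(t, j);
      for (int i = 0; i < m; ++i) {
        const double grow_out = (i == m - 1) ? 0.0 : g;  // no growth off grid
        double x = (1.0 - grow_out - delta(i, j)) * w(i, j);
        if (i > 0) x += g * w(i - 1, j);
        if (i + p < m) x += 2.0 * delta(i + p, j) * w(i + p, j);
        neww[i] = x;
      }
      for (int i = 0; i < m; ++i) w(i, j) = neww[i];
    }
  }

  for (int j = 0; j < s; ++j)
    for (int i = 0; i < m; ++i) nsub_end[j] += w(i, j);

  double n_start = 0.0, n_end = 0.0;
  for (int j = 0; j < s; ++j) { n_start += nsub_start[j]; n_end += nsub_end[j]; }
  return List::create(_["q"] = q,
                      _["n_start"] = n_start,
                      _["n_end"] = n_end,
                      _["nsub_start"] = nsub_start,
                      _["nsub_end"] = nsub_end,
                      _["w_final"] = w);
}
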