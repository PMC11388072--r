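#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Quality-aware gapless realignment of a soft-clipped sequence against a
// search window. For every start offset the log-likelihood is
//   sum over bases of log(1 - eps_b)        for a match
//                    log(eps_b / 3)         for a mismatch
// with eps_b decoded from the base quality. The posterior of the best
// offset is its likelihood over the sum across all scanned offsets
// (offsets falling more than `drop` nats below the running best are
// abandoned early; their contribution to the denominator is negligible
// by construction). Ambiguous bases ('N' on either side) contribute
// log(0.25) regardless of match status.
//
// [[Rcpp::export]]
List realign_scan_cpp(std::string clip, NumericVector eps, std::string window,
                      double drop = 34.5) {
  const int m = clip.size();
  const int W = window.size();
  const int nposs = W - m + 1;
  if (nposs <= 0 || m == 0) {
    return List::create(_["offset"] = -1, _["posterior"] = 0.0,
                        _["n_positions"] = 0);
  }
  std::vector<double> lmatch(m), lmis(m);
  for (int j = 0; j < m; ++j) {
    double e = eps[j];
    if (e < 1e-6) e = 1e-6;
    if (e > 0.75) e = 0.75;
    lmatch[j] = std::log(1.0 - e);
    lmis[j] = std::log(e / 3.0);
  }
  const double lamb = std::log(0.25);
  std::vector<double> ll(nposs, R_NegInf);
  double best = R_NegInf;
  int best_at = -1;
  for (int s = 0; s < nposs; ++s) {
    double acc = 0.0;
    const double cut = best - drop;
    bool alive = true;
    for (int j = 0; j < m; ++j) {
      const char a = clip[j];
      const char b = window[s + j];
      if (a == 'N' || b == 'N') acc += lamb;
      else if (a == b) acc += lmatch[j];
      else acc += lmis[j];
      if (acc < cut) { alive = false; break; }
    }
    if (!alive) continue;
    ll[s] = acc;
    if (acc > best) { best = acc; best_at = s; }
  }
  if (best_at < 0) {
    return List::create(_["offset"] = -1, _["posterior"] = 0.0,
                        _["n_positions"] = nposs);
  }
  // log-sum-exp over surviving offsets
  double denom = 0.0;
  for (int s = 0; s < nposs; ++s) {
    if (ll[s] > R_NegInf) denom += std::exp(ll[s] - best);
  }
  return List::create(_["offset"] = best_at,
                      _["posterior"] = 1.0 / denom,
                      _["n_positions"] = nposs);
}
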