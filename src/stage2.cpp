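#include <Rcpp.h>
using namespace Rcpp;

// Depth-first enumeration of per-site species tuples whose summed
// 4-unit composition equals the target exactly. Pruning: a partial tuple
// is abandoned when any unit count overshoots the target or when the
// remaining sites cannot supply the remaining counts (suffix maxima).
//
// unit_mats: list of integer matrices (n_species x 4) per site
// abundances: list of numeric vectors per site
// target: integer vector length 4
// suffix_max: (k+1) x 4 matrix of cumulative per-unit maxima from the back
//
// Returns list(picks = IntegerMatrix n x k (1-based), raw = NumericVector).
// [[Rcpp::export(name = ".dfs_assign")]]
List dfs_assign(List unit_mats, List abundances, IntegerVector target,
                IntegerMatrix suffix_max) {
  const int k = unit_mats.size();
  std::vector<IntegerMatrix> mats(k);
  std::vector<NumericVector> abs_(k);
  for (int s = 0; s < k; ++s) {
    mats[s] = as<IntegerMatrix>(unit_mats[s]);
    abs_[s] = as<NumericVector>(abundances[s]);
  }
  std::vector<int> pick(k, 0);
  std::vector<int> out_picks;
  std::vector<double> out_raw;

  // iterative DFS with explicit stack of (depth, species index)
  std::vector<int> rem(4);
  for (int u = 0; u < 4; ++u) rem[u] = target[u];

  std::function<void(int, double)> rec = [&](int depth, double raw) {
    if (depth == k) {
      if (rem[0] == 0 && rem[1] == 0 && rem[2] == 0 && rem[3] == 0) {
        for (int s = 0; s < k; ++s) out_picks.push_back(pick[s] + 1);
        out_raw.push_back(raw);
      }
      return;
    }
    const IntegerMatrix& m = mats[depth];
    const NumericVector& a = abs_[depth];
    const int n = m.nrow();
    for (int j = 0; j < n; ++j) {
      bool ok = true;
      for (int u = 0; u < 4; ++u) {
        int r = rem[u] - m(j, u);
        if (r < 0 || r > suffix_max(depth + 1, u)) { ok = false; break; }
      }
      if (!ok) continue;
      for (int u = 0; u < 4; ++u) rem[u] -= m(j, u);
      pick[depth] = j;
      rec(depth + 1, raw * a[j]);
      for (int u = 0; u < 4; ++u) rem[u] += m(j, u);
    }
  };
  rec(0, 1.0);

  const int nres = out_raw.size();
  IntegerMatrix picks(nres, k);
  for (int r = 0; r < nres; ++r)
    for (int s = 0; s < k; ++s) picks(r, s) = out_picks[(size_t)r * k + s];
  return List::create(_["picks"] = picks,
                      _["raw"] = NumericVector(out_raw.begin(), out_raw.end()));
}
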