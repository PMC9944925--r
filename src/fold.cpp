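#include <Rcpp.h>
using namespace Rcpp;

// Pair-additive secondary-structure energy model.
// Sequences arrive encoded as integers: A=0, C=1, G=2, U=3.
// Canonical pair set: GC/CG, AU/UA, GU/UG (wobble included).

static inline double pairEnergy(int a, int b, double eGC, double eAU, double eGU) {
  // returns NA_REAL for non-canonical combinations
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return eGC;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return eAU;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return eGU;
  return NA_REAL;
}

// [[Rcpp::export(name = ".cpp_eval_energy")]]
List cpp_eval_energy(IntegerVector seq, IntegerMatrix pairs,
                     double eGC, double eAU, double eGU, double penalty) {
  double energy = 0.0;
  int incompat = 0;
  for (int r = 0; r < pairs.nrow(); ++r) {
    int i = pairs(r, 0) - 1, j = pairs(r, 1) - 1;
    double e = pairEnergy(seq[i], seq[j], eGC, eAU, eGU);
    if (ISNA(e)) { energy += penalty; ++incompat; }
    else energy += e;
  }
  return List::create(_["energy"] = energy, _["incompatible"] = incompat);
}

// Minimum over all nested canonical structures of the pairwise-additive
// energy; O(n^3) interval DP. Deterministic traceback: position i is left
// unpaired whenever that ties the optimum; among pairing partners the
// smallest k is preferred.
// [[Rcpp::export(name = ".cpp_mfe")]]
List cpp_mfe(IntegerVector seq, double eGC, double eAU, double eGU, int minLoop) {
  const int n = seq.size();
  const double TOL = 1e-9;
  // E[i][j] over 0-based closed intervals, stored as flat n x n (j >= i)
  std::vector<double> E((size_t)n * n, 0.0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[idx(i + 1, j)];  // i unpaired
      for (int k = i + minLoop + 1; k <= j; ++k) {
        double e = pairEnergy(seq[i], seq[k], eGC, eAU, eGU);
        if (ISNA(e)) continue;
        double cand = e + (k - 1 >= i + 1 ? E[idx(i + 1, k - 1)] : 0.0)
                        + (k + 1 <= j ? E[idx(k + 1, j)] : 0.0);
        if (cand < best - TOL) best = cand;
      }
      E[idx(i, j)] = best;
    }
  }

  // traceback
  std::vector<int> pi, pj;
  std::vector<std::pair<int, int> > stack;
  if (n > 1) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    double tgt = E[idx(i, j)];
    if (std::abs(E[idx(i + 1, j)] - tgt) <= TOL) {  // prefer i unpaired
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    bool found = false;
    for (int k = i + minLoop + 1; k <= j && !found; ++k) {
      double e = pairEnergy(seq[i], seq[k], eGC, eAU, eGU);
      if (ISNA(e)) continue;
      double cand = e + (k - 1 >= i + 1 ? E[idx(i + 1, k - 1)] : 0.0)
                      + (k + 1 <= j ? E[idx(k + 1, j)] : 0.0);
      if (std::abs(cand - tgt) <= TOL) {
        pi.push_back(i + 1); pj.push_back(k + 1);
        if (k - 1 >= i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        found = true;
      }
    }
    if (!found) stop("traceback failed: inconsistent DP table");
  }

  IntegerMatrix pm(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) { pm(r, 0) = pi[r]; pm(r, 1) = pj[r]; }
  return List::create(_["energy"] = (n > 1 ? E[idx(0, n - 1)] : 0.0),
                      _["pairs"] = pm);
}

// delta = E(target | seq) - E(MFE | seq); used in the MC inner loop where
// allocating S4 results per step would dominate the run time.
// [[Rcpp::export(name = ".cpp_delta")]]
List cpp_delta(IntegerVector seq, IntegerMatrix target,
               double eGC, double eAU, double eGU, double penalty, int minLoop) {
  List ev = cpp_eval_energy(seq, target, eGC, eAU, eGU, penalty);
  List mf = cpp_mfe(seq, eGC, eAU, eGU, minLoop);
  double te = ev["energy"], me = mf["energy"];
  return List::create(_["target_energy"] = te,
                      _["mfe_energy"] = me,
                      _["delta"] = te - me,
                      _["incompatible"] = as<int>(ev["incompatible"]));
}
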