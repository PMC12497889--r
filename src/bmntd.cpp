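// Core loops for betaMNTD and its tip-shuffle null distribution. The null
// model permutes taxon labels on the cophenetic matrix once per replicate and
// shares that permutation across all sample pairs, so the whole pairwise
// betaMNTD matrix is recomputed n_null times; this is the hot path.
//
// Key shortcut: a taxon present in both communities has itself as nearest
// neighbour (distance 0) under the identity and under any label permutation
// (D(lab[i], lab[j]) = 0 iff i == j), so only taxa in the set difference of
// the two communities contribute, and only they need a distance scan.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Community {
  std::vector<int> present;   // taxon indices with abundance > 0
  std::vector<double> weight; // relative weight per present taxon (sums to 1)
};

struct PairPlan {
  // taxa of a not in b (and their weights), and vice versa
  std::vector<int> only_a, only_b;
  std::vector<double> w_only_a, w_only_b;
};

static void build_communities(const NumericMatrix& W, bool weighted,
                              std::vector<Community>& com) {
  const int n = W.nrow(), t = W.ncol();
  com.assign(n, Community());
  for (int s = 0; s < n; ++s) {
    double tot = 0.0;
    for (int k = 0; k < t; ++k) {
      if (W(s, k) > 0) { com[s].present.push_back(k); tot += W(s, k); }
    }
    const size_t ns = com[s].present.size();
    com[s].weight.resize(ns);
    for (size_t k = 0; k < ns; ++k) {
      com[s].weight[k] = weighted ? W(s, com[s].present[k]) / tot : 1.0 / ns;
    }
  }
}

static PairPlan plan_pair(const Community& a, const Community& b, int t) {
  std::vector<char> in_b(t, 0), in_a(t, 0);
  for (int j : b.present) in_b[j] = 1;
  for (int i : a.present) in_a[i] = 1;
  PairPlan p;
  for (size_t k = 0; k < a.present.size(); ++k) {
    if (!in_b[a.present[k]]) {
      p.only_a.push_back(a.present[k]);
      p.w_only_a.push_back(a.weight[k]);
    }
  }
  for (size_t k = 0; k < b.present.size(); ++k) {
    if (!in_a[b.present[k]]) {
      p.only_b.push_back(b.present[k]);
      p.w_only_b.push_back(b.weight[k]);
    }
  }
  return p;
}

// betaMNTD for one pair under label permutation `lab` (identity for the
// observed value): 0.5 * (sum over a-only taxa of w * min dist to b
//                        + sum over b-only taxa of w * min dist to a).
static double pair_bmntd(const PairPlan& p, const Community& a,
                         const Community& b, const NumericMatrix& D,
                         const std::vector<int>& lab) {
  double acc = 0.0;
  for (size_t k = 0; k < p.only_a.size(); ++k) {
    const int ti = lab[p.only_a[k]];
    double mn = R_PosInf;
    for (int j : b.present) {
      const double d = D(ti, lab[j]);
      if (d < mn) mn = d;
    }
    acc += p.w_only_a[k] * mn;
  }
  for (size_t k = 0; k < p.only_b.size(); ++k) {
    const int tj = lab[p.only_b[k]];
    double mn = R_PosInf;
    for (int i : a.present) {
      const double d = D(tj, lab[i]);
      if (d < mn) mn = d;
    }
    acc += p.w_only_b[k] * mn;
  }
  return 0.5 * acc;
}

// [[Rcpp::export]]
NumericMatrix bmntd_matrix_cpp(NumericMatrix W, NumericMatrix D, bool weighted) {
  const int n = W.nrow(), t = W.ncol();
  std::vector<Community> com;
  build_communities(W, weighted, com);
  std::vector<int> identity(t);
  for (int k = 0; k < t; ++k) identity[k] = k;
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      const PairPlan p = plan_pair(com[a], com[b], t);
      const double v = pair_bmntd(p, com[a], com[b], D, identity);
      out(a, b) = v;
      out(b, a) = v;
    }
  }
  return out;
}

// perms: n_null x n_taxa, 0-based label permutations. Returns observed
// betaMNTD plus null mean and sd per pair (upper-triangle order, a < b).
// [[Rcpp::export]]
List bnti_null_cpp(NumericMatrix W, NumericMatrix D, IntegerMatrix perms,
                   bool weighted) {
  const int n = W.nrow(), n_null = perms.nrow(), t = D.nrow();
  std::vector<Community> com;
  build_communities(W, weighted, com);
  const int n_pairs = n * (n - 1) / 2;
  std::vector<PairPlan> plans;
  plans.reserve(n_pairs);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      plans.push_back(plan_pair(com[a], com[b], t));
  NumericVector obs(n_pairs), mean_null(n_pairs), sd_null(n_pairs);
  std::vector<double> sum(n_pairs, 0.0), sumsq(n_pairs, 0.0);
  std::vector<int> lab(t);
  for (int k = 0; k < t; ++k) lab[k] = k;
  int pp = 0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b, ++pp)
      obs[pp] = pair_bmntd(plans[pp], com[a], com[b], D, lab);
  for (int r = 0; r < n_null; ++r) {
    for (int k = 0; k < t; ++k) lab[k] = perms(r, k);
    pp = 0;
    for (int a = 0; a < n; ++a) {
      for (int b = a + 1; b < n; ++b, ++pp) {
        const double v = pair_bmntd(plans[pp], com[a], com[b], D, lab);
        sum[pp] += v;
        sumsq[pp] += v * v;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  for (int k = 0; k < n_pairs; ++k) {
    const double mu = sum[k] / n_null;
    double var = (sumsq[k] - n_null * mu * mu) / (n_null - 1);
    if (var < 0) var = 0;
    mean_null[k] = mu;
    sd_null[k] = std::sqrt(var);
  }
  return List::create(_["obs"] = obs, _["null_mean"] = mean_null,
                      _["null_sd"] = sd_null);
}
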