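#include <Rcpp.h>
using namespace Rcpp;

// Size-biased pick among the first m entries of s, skipping index `skip`
// (pass -1 for no skip). `total` must equal the summed weight of eligible
// entries. Uses R's global RNG so set.seed() governs reproducibility.
static inline int pick_weighted(const std::vector<int>& s, int m,
                                double total, int skip) {
  double u = unif_rand() * total, acc = 0.0;
  for (int i = 0; i < m; ++i) {
    if (i == skip) continue;
    acc += s[i];
    if (u < acc) return i;
  }
  for (int i = m - 1; i >= 0; --i)  // guard against rounding at u ~ total
    if (i != skip) return i;
  return -1;
}

// Uniform unordered pair of distinct indices in [0, m).
static inline void pick_equal(int m, int& a, int& b) {
  a = (int)(unif_rand() * m);
  if (a >= m) a = m - 1;
  b = (int)(unif_rand() * (m - 1));
  if (b >= m - 1) b = m - 2;
  if (b >= a) ++b;
}

static inline void pick_pair(const std::vector<int>& s, int m, double total,
                             bool weighted, int& a, int& b) {
  if (weighted) {
    a = pick_weighted(s, m, total, -1);
    b = pick_weighted(s, m, total - s[a], a);
  } else {
    pick_equal(m, a, b);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_draw_pairs(IntegerVector sizes, int ndraw, bool weighted) {
  int m = sizes.size();
  if (m < 2) stop("need at least 2 cells to draw a fusion pair");
  std::vector<int> s(sizes.begin(), sizes.end());
  double total = 0.0;
  for (int i = 0; i < m; ++i) {
    if (s[i] < 1) stop("cell sizes must be positive integers");
    total += s[i];
  }
  IntegerMatrix out(ndraw, 2);
  int a, b;
  for (int k = 0; k < ndraw; ++k) {
    pick_pair(s, m, total, weighted, a, b);
    out(k, 0) = a + 1;
    out(k, 1) = b + 1;
  }
  return out;
}

// Replay a fusion schedule from N singletons, recording after each interval
// the fraction of nuclei residing in cells with >= threshold nuclei. With
// cap_statistic the annotation distortion is applied: every cell contributes
// min(size, cap) nuclei to both numerator and denominator.
// [[Rcpp::export]]
NumericVector cpp_simulate_replicate(int N, IntegerVector n_fusion,
                                     bool weighted, int threshold, int cap,
                                     bool cap_statistic) {
  int T = n_fusion.size();
  std::vector<int> s((size_t)N, 1);
  int m = N;
  double total = N;  // nuclei are conserved by fusion
  NumericVector f4(T);
  for (int t = 0; t < T; ++t) {
    int k = n_fusion[t];
    int a, b;
    for (int e = 0; e < k; ++e) {
      if (m < 2) stop("population exhausted: fusion schedule is infeasible");
      pick_pair(s, m, total, weighted, a, b);
      s[a] += s[b];
      s[b] = s[m - 1];  // if a was the last slot the merged cell moves to b
      --m;
    }
    double num = 0.0, den = 0.0;
    if (cap_statistic) {
      for (int i = 0; i < m; ++i) {
        int eff = s[i] < cap ? s[i] : cap;
        den += eff;
        if (s[i] >= threshold) num += eff;
      }
    } else {
      den = (double)N;
      for (int i = 0; i < m; ++i)
        if (s[i] >= threshold) num += s[i];
    }
    f4[t] = num / den;
  }
  return f4;
}
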