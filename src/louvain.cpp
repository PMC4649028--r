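#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy node-moving + aggregation (generalized Louvain) on a dense
// symmetric quality matrix B. The quality of a partition H is
// Q = trace(H^T B H) = sum over communities c of sum_{i,j in c} B(i,j).
// Diagonal entries contribute to every partition equally and are ignored
// for move gains. `order` (0-based) fixes the sweep order of the first
// level, so results are deterministic given it.

static std::vector<int> one_level(const std::vector<double> &B, int n,
                                  const std::vector<int> &order,
                                  bool &improved) {
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = i;
  improved = false;
  bool moved = true;
  int pass = 0;
  while (moved && pass < 100) {
    moved = false;
    ++pass;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      // link strength from i to every community (excluding i itself)
      std::vector<double> s(n, 0.0);
      const double *row = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        s[comm[j]] += row[j];
      }
      int best = comm[i];
      double best_gain = 0.0;
      double s_own = s[comm[i]];
      for (int c = 0; c < n; ++c) {
        if (c == comm[i]) continue;
        double gain = s[c] - s_own;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best = c;
        }
      }
      if (best != comm[i]) {
        comm[i] = best;
        moved = true;
        improved = true;
      }
    }
  }
  return comm;
}

// [[Rcpp::export]]
IntegerVector louvain_dense(NumericMatrix Bmat, IntegerVector order0) {
  int n = Bmat.nrow();
  std::vector<double> B(Bmat.begin(), Bmat.end());
  std::vector<int> membership(n);
  for (int i = 0; i < n; ++i) membership[i] = i;
  std::vector<int> order(order0.begin(), order0.end());
  int ncur = n;
  bool improved = true;
  int level = 0;
  while (improved && ncur > 1 && level < 100) {
    ++level;
    std::vector<int> comm = one_level(B, ncur, order, improved);
    // relabel communities contiguously
    std::vector<int> relab(ncur, -1);
    int k = 0;
    for (int i = 0; i < ncur; ++i)
      if (relab[comm[i]] < 0) relab[comm[i]] = k++;
    for (int i = 0; i < ncur; ++i) comm[i] = relab[comm[i]];
    // project onto original nodes
    for (int i = 0; i < n; ++i) membership[i] = comm[membership[i]];
    if (!improved || k == ncur) break;
    // aggregate B
    std::vector<double> B2((size_t)k * k, 0.0);
    for (int i = 0; i < ncur; ++i)
      for (int j = 0; j < ncur; ++j)
        B2[(size_t)comm[i] * k + comm[j]] += B[(size_t)i * ncur + j];
    B.swap(B2);
    ncur = k;
    order.resize(ncur);
    for (int i = 0; i < ncur; ++i) order[i] = i;  // deterministic upper levels
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = membership[i] + 1;  // 1-based labels
  return out;
}
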